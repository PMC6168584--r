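# Default seasonal-adjustment configuration. Vitamin D shows a summer
# elevation; measurements drawn June-September are adjusted down by the
# regression-estimated offset before change testing. The default offset of
# 2.5 (same units as the biomarker) is the conventional planted value used
# by the synthetic-cohort presets; on real data the offset is re-estimated
# with fitSeasonalModel().
biomarker: VITD
summer_months: [6, 7, 8, 9]
offset: 2.5
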