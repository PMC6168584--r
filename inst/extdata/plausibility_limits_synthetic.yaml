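# Synthetic default plausibility limits (lower/upper bounds on acceptable
# values, inclusive). These defaults were constructed from the marginal
# distributions of the package's synthetic "full" preset (roughly the
# central 99.5% of each marginal, floored at 0 for nonnegative analytes);
# they are NOT derived from any population survey. For real data, derive
# limits from a reference sample with deriveLimits() instead.
VITD: {lower: 2, upper: 62}
LDL: {lower: 20, upper: 200}
CK: {lower: 0, upper: 340}
GLU: {lower: 60, upper: 120}
HDL: {lower: 13, upper: 97}
CHOL: {lower: 85, upper: 295}
ALT: {lower: 0, upper: 53}
TG: {lower: 0, upper: 245}
CORT: {lower: 0.5, upper: 27.5}
FERR: {lower: 0, upper: 220}
HSCRP: {lower: 0, upper: 4.9}
AST: {lower: 0, upper: 48}
TESTO: {lower: 50, upper: 950}
EOS: {lower: 0, upper: 340}
MCHC: {lower: 30.2, upper: 36.8}
SHBG: {lower: 0, upper: 82}
FTESTO: {lower: 4, upper: 136}
WBC: {lower: 1.7, upper: 11.3}
NEUT: {lower: 0.2, upper: 7.4}
LYMPH: {lower: 0.2, upper: 3.8}
MONO: {lower: 0.05, upper: 0.95}
BASO: {lower: 0, upper: 0.11}
RBC: {lower: 3.6, upper: 6.0}
HGB: {lower: 10.6, upper: 18.4}
HCT: {lower: 32.5, upper: 53.5}
MCV: {lower: 75.5, upper: 102.5}
MCH: {lower: 24, upper: 36}
PLT: {lower: 85, upper: 415}
RDW: {lower: 10.5, upper: 15.9}
SODIUM: {lower: 133.4, upper: 146.6}
POTASSIUM: {lower: 3.25, upper: 5.35}
CALCIUM: {lower: 8.3, upper: 10.7}
MAGNESIUM: {lower: 1.51, upper: 2.59}
B12: {lower: 40, upper: 1060}
FOLATE: {lower: 1.5, upper: 28.5}
IRON: {lower: 1, upper: 199}
TIBC: {lower: 185, upper: 455}
TSAT: {lower: 0, upper: 60}
DHEAS: {lower: 0, upper: 410}
TSH: {lower: 0, upper: 3.6}
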