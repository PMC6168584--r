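.defaultRunConfig <- function() {
    seas <- loadSeasonalDefaults()
    list(measurements = NULL, participants = NULL, interventions = NULL,
         range_rules = NULL, plausibility_limits = NULL,
         min_gap_days = 30, pair_strategy = "earliest",
         min_n = 10, alpha = 0.05,
         linkage = "average", min_cluster_size = 3,
         cut_height_fraction = 0.99, split_gap_fraction = 0.35,
         seasonal_biomarker = seas$biomarker,
         summer_months = seas$summer_months,
         min_group = 20,
         scan_biomarkers = c("VITD", "LDL"), top_k = 10, B = 10000,
         seed = NULL, output_dir = NULL)
}

.stageStop <- function(stage, e, output_dir) {
    rec <- list(stage = stage, message = conditionMessage(e))
    if (!is.null(output_dir) && dir.exists(output_dir))
        jsonlite::write_json(rec, file.path(output_dir, "error.json"),
                             auto_unbox = TRUE)
    stop(errorCondition(paste0("stage '", stage, "' failed: ",
                               conditionMessage(e)),
                        stage = stage,
                        class = "biodeltaStageError"))
}

#' Run the full longitudinal analysis pipeline
#'
#' Executes every stage end-to-end: quality filtering, seasonal adjustment,
#' the delta-correlation network, community detection, the change tables,
#' and the intervention scan; writes every intermediate artifact plus a
#' run manifest to the output directory. Rerunning with an identical config
#' and inputs reproduces identical artifacts. Any stage error halts the run
#' with the stage name (condition class `biodeltaStageError`) and a
#' machine-readable `error.json`.
#'
#' @param config named list, or path to a YAML file, with entries:
#'   `measurements`, `participants`, `interventions` (input CSV paths;
#'   interventions optional), `range_rules` / `plausibility_limits`
#'   (config paths, `NULL` for bundled defaults), `min_gap_days`,
#'   `pair_strategy`, `min_n`, `alpha`, `linkage`, `min_cluster_size`,
#'   `cut_height_fraction`, `split_gap_fraction`, `seasonal_biomarker`,
#'   `summer_months`, `min_group`, `scan_biomarkers`, `top_k`, `B`,
#'   `seed` (mandatory: drives the Monte-Carlo stage), `output_dir`.
#' @return the run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    ## fail-fast validation before any compute
    for (f in c("measurements", "participants")) {
        if (is.null(cfg[[f]]))
            stop("config error: '", f, "' input path is required")
        if (!file.exists(cfg[[f]]))
            stop("config error: '", f, "' path does not exist: ", cfg[[f]])
    }
    for (f in c("interventions", "range_rules", "plausibility_limits"))
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            stop("config error: '", f, "' path does not exist: ", cfg[[f]])
    if (is.null(cfg$seed))
        stop("config error: an explicit 'seed' is required")
    if (is.null(cfg$output_dir))
        stop("config error: 'output_dir' is required")
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(name) file.path(cfg$output_dir, name)
    stages <- list(); files <- character()

    ## -- stage qc: read, pair, plausibility-filter ----------------------
    qc <- tryCatch({
        tab <- readMeasurements(cfg$measurements, cfg$participants)
        pairs <- extractPairs(tab, min_gap_days = cfg$min_gap_days,
                              strategy = cfg$pair_strategy)
        limits <- loadLimits(cfg$plausibility_limits)
        filt <- applyLimits(pairs, limits)
        writeExclusionReport(filt$report, out("qc_exclusions.csv"))
        list(table = tab, pairs = filt$pairs, report = filt$report)
    }, error = function(e) .stageStop("qc", e, cfg$output_dir))
    files <- c(files, "qc_exclusions.csv")
    stages$qc <- list(n_measurements = nrow(measurements(qc$table)),
                      n_participants = nrow(participants(qc$table)),
                      n_pairs = nrow(qc$pairs),
                      n_removed = sum(qc$report$n_removed))

    ## -- stage seasonal: fit summer offset, adjust pairs ----------------
    seasonal <- tryCatch({
        mm <- measurements(qc$table)
        sub <- mm[mm$biomarker == cfg$seasonal_biomarker, , drop = FALSE]
        model <- tryCatch(
            fitSeasonalModel(sub$value, sub$draw_date,
                             biomarker = cfg$seasonal_biomarker,
                             summer_months = cfg$summer_months),
            error = function(e) NULL)
        pairs <- if (is.null(model)) qc$pairs
                 else applySeasonalAdjustment(qc$pairs, model)
        jsonlite::write_json(
            if (is.null(model)) list(skipped = TRUE)
            else model, out("seasonal_model.json"),
            auto_unbox = TRUE, digits = NA)
        list(model = model, pairs = pairs)
    }, error = function(e) .stageStop("seasonal", e, cfg$output_dir))
    files <- c(files, "seasonal_model.json")
    stages$seasonal <- list(
        fitted = !is.null(seasonal$model),
        offset_estimate = if (is.null(seasonal$model)) NA
                          else seasonal$model$offset_estimate)

    ## -- stage network: deltas, correlations, significant edges ---------
    net <- tryCatch({
        dm <- deltaMatrix(seasonal$pairs, participants(qc$table))
        entries <- correlateAll(dm, min_n = cfg$min_n)
        network <- buildNetwork(entries, alpha = cfg$alpha)
        writeCorrelationTable(entries, out("correlation_table.csv"))
        writeEdgeList(network, out("network_edges.tsv"))
        writeGraphML(network, out("network.graphml"))
        list(dm = dm, entries = entries, network = network)
    }, error = function(e) .stageStop("network", e, cfg$output_dir))
    files <- c(files, "correlation_table.csv", "network_edges.tsv",
               "network.graphml")
    stages$network <- list(n_tested_pairs = nrow(net$entries),
                           n_untested = nrow(attr(net$entries, "untested")),
                           n_edges = nrow(networkEdges(net$network)))

    ## -- stage cluster: 1 - |rho| distance, adaptive tree cut -----------
    clus <- tryCatch({
        D <- suppressWarnings(distanceFromCorrelations(net$entries))
        dend <- hierarchicalCluster(D, linkage = cfg$linkage)
        assignment <- dynamicTreeCut(
            dend, D, min_cluster_size = cfg$min_cluster_size,
            cut_height_fraction = cfg$cut_height_fraction,
            split_gap_fraction = cfg$split_gap_fraction)
        writeClusterAssignment(assignment, out("clusters.csv"))
        writeGraphML(net$network, out("network_clusters.graphml"),
                     clusters = assignment)
        assignment
    }, error = function(e) .stageStop("cluster", e, cfg$output_dir))
    files <- c(files, "clusters.csv", "network_clusters.graphml")
    stages$cluster <- list(
        n_clusters = length(setdiff(unique(clus), 0L)),
        n_unassigned = sum(clus == 0L))

    ## -- stage changes: out-of-range and full-population tables ---------
    chg <- tryCatch({
        rules <- loadRangeRules(cfg$range_rules)
        oor <- outOfRangeChangeTable(seasonal$pairs, rules,
                                     participants(qc$table),
                                     min_group = cfg$min_group,
                                     group = "out_of_range")
        all_tab <- outOfRangeChangeTable(seasonal$pairs, rules,
                                         participants(qc$table),
                                         min_group = cfg$min_group,
                                         group = "all")
        writeChangeTable(oor, out("change_table_out_of_range.csv"))
        writeChangeTable(all_tab, out("change_table_all.csv"))
        p <- participants(qc$table)
        bmi <- if (all(c("bmi_baseline", "bmi_followup") %in% names(p)) &&
                   sum(stats::complete.cases(
                       p[, c("bmi_baseline", "bmi_followup")])) >= 2)
            pairedTTest(p$bmi_baseline[!is.na(p$bmi_baseline) &
                                       !is.na(p$bmi_followup)],
                        p$bmi_followup[!is.na(p$bmi_baseline) &
                                       !is.na(p$bmi_followup)])
        else NULL
        list(oor = oor, all = all_tab, rules = rules, bmi = bmi)
    }, error = function(e) .stageStop("changes", e, cfg$output_dir))
    files <- c(files, "change_table_out_of_range.csv",
               "change_table_all.csv")
    stages$changes <- list(
        n_rows_out_of_range = nrow(chg$oor),
        n_omitted = nrow(attr(chg$oor, "omitted")),
        bmi_mean_change = if (is.null(chg$bmi)) NA else chg$bmi$mean_change,
        bmi_p = if (is.null(chg$bmi)) NA else chg$bmi$p)

    ## -- stage interventions: choice-vs-improvement scan ----------------
    scan <- tryCatch({
        if (is.null(cfg$interventions)) {
            NULL
        } else {
            choices <- readInterventions(cfg$interventions)
            defs <- improvementDefinitions(
                chg$rules,
                intersect(cfg$scan_biomarkers,
                          unique(seasonal$pairs$biomarker)))
            sc <- interventionScan(seasonal$pairs, choices, defs,
                                   top_k = cfg$top_k, B = cfg$B,
                                   seed = cfg$seed)
            writeInterventionScan(sc, out("intervention_scan.csv"))
            sc
        }
    }, error = function(e) .stageStop("interventions", e, cfg$output_dir))
    if (!is.null(scan)) files <- c(files, "intervention_scan.csv")
    stages$interventions <- if (is.null(scan)) list(skipped = TRUE)
        else list(n_tests = nrow(scan),
                  n_nominal = sum(scan$nominal, na.rm = TRUE),
                  n_significant_q = sum(scan$q < 0.05, na.rm = TRUE))

    ## -- manifest -------------------------------------------------------
    cfg_path <- out("run_config.yaml")
    yaml::write_yaml(cfg, cfg_path)
    files <- c(files, "run_config.yaml")
    manifest <- list(
        package_version = as.character(packageVersion("biodelta")),
        seed = cfg$seed,
        config = cfg,
        config_md5 = unname(tools::md5sum(cfg_path)),
        stages = stages,
        files = sort(c(files, "manifest.json")))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Write a synthetic demo cohort to disk
#'
#' Generates a preset synthetic cohort (see [syntheticPreset()]) and writes
#' it in the package's interchange formats — `measurements.csv`,
#' `participants.csv`, `interventions.csv` — plus the planted-truth record
#' as `truth.json`, for tutorials and tests.
#'
#' @param preset preset name (`"full"`, `"tiny"`, `"null"`).
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
makeDemoData <- function(preset = "tiny", seed = 1, dir) {
    config <- syntheticPreset(preset, seed = seed)
    cohort <- generateCohort(config)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(measurements = file.path(dir, "measurements.csv"),
               participants = file.path(dir, "participants.csv"),
               interventions = file.path(dir, "interventions.csv"),
               truth = file.path(dir, "truth.json"))
    writeMeasurements(cohort$table, paths["measurements"],
                      paths["participants"])
    write.csv(cohort$choices, paths["interventions"], row.names = FALSE,
              quote = FALSE)
    truth <- cohort$truth
    truth$blocks <- as.list(truth$blocks)
    truth$seasonal_offsets <- as.list(truth$seasonal_offsets)
    truth$panel <- as.list(truth$panel)
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}
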