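#' Construct a MeasurementTable
#'
#' Assembles and validates a \linkS4class{MeasurementTable} from a long-format
#' measurement data.frame and an optional participant table. When no
#' participant table is given, a minimal one (unknown sex and age) is derived
#' from the participant identifiers present in the measurements.
#'
#' @param measurements data.frame with columns `participant_id`, `biomarker`,
#'   `value`, `draw_date` (`Date` or ISO-8601 strings).
#' @param participants optional data.frame with columns `participant_id`,
#'   `sex`, `age_years` and optional `bmi_baseline`, `bmi_followup`.
#' @return A validated `MeasurementTable`.
#' @export
measurementTable <- function(measurements, participants = NULL) {
    measurements <- as.data.frame(measurements)
    if (!inherits(measurements$draw_date, "Date"))
        measurements$draw_date <- as.Date(measurements$draw_date)
    measurements$participant_id <- as.character(measurements$participant_id)
    measurements$biomarker <- as.character(measurements$biomarker)
    if (is.null(participants)) {
        ids <- unique(measurements$participant_id)
        participants <- data.frame(participant_id = ids,
                                   sex = rep(NA_character_, length(ids)),
                                   age_years = rep(NA_real_, length(ids)),
                                   bmi_baseline = rep(NA_real_, length(ids)),
                                   bmi_followup = rep(NA_real_, length(ids)))
    }
    participants <- as.data.frame(participants)
    participants$participant_id <- as.character(participants$participant_id)
    for (col in setdiff(.PARTICIPANT_COLS, names(participants)))
        participants[[col]] <- if (col == "sex") NA_character_ else NA_real_
    new("MeasurementTable",
        measurements = measurements[, .MEASUREMENT_COLS],
        participants = participants[, .PARTICIPANT_COLS])
}

#' Read a long-format measurements CSV
#'
#' Reads a measurements CSV (columns `participant_id,biomarker,value,draw_date`
#' with ISO-8601 dates) into a \linkS4class{MeasurementTable}. Rows whose
#' value is non-numeric or whose date does not parse are not silently
#' dropped: they are removed from the table and reported, with their original
#' row numbers and the offending field, in the `"rejected"` attribute of the
#' returned object's measurement table (also emitted as a warning).
#'
#' @param path path to the measurements CSV.
#' @param participants_path optional path to a participants CSV (columns
#'   `participant_id,sex,age_years,bmi_baseline,bmi_followup`).
#' @return A `MeasurementTable`; `attr(measurements(x), "rejected")` holds the
#'   per-row rejection report (zero rows when everything parsed).
#' @export
readMeasurements <- function(path, participants_path = NULL) {
    if (!file.exists(path))
        stop("measurements file does not exist: ", path)
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    missing_cols <- setdiff(.MEASUREMENT_COLS, names(raw))
    if (length(missing_cols))
        stop("measurements CSV is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    value <- suppressWarnings(as.numeric(raw$value))
    date <- suppressWarnings(as.Date(raw$draw_date, format = "%Y-%m-%d"))
    bad_value <- is.na(value) | !is.finite(value)
    bad_date <- is.na(date)
    bad <- bad_value | bad_date
    rejected <- data.frame(
        row = which(bad),
        participant_id = raw$participant_id[bad],
        biomarker = raw$biomarker[bad],
        reason = ifelse(bad_value[bad], "unparseable value",
                        "unparseable draw_date"),
        stringsAsFactors = FALSE)
    if (nrow(rejected))
        warning(nrow(rejected), " row(s) rejected while reading ", path,
                "; see attr(measurements(x), 'rejected')")
    m <- data.frame(participant_id = raw$participant_id[!bad],
                    biomarker = raw$biomarker[!bad],
                    value = value[!bad],
                    draw_date = date[!bad],
                    stringsAsFactors = FALSE)
    key <- paste(m$participant_id, m$biomarker, m$draw_date, sep = "\r")
    if (anyDuplicated(key)) {
        offenders <- m[duplicated(key) | duplicated(key, fromLast = TRUE), ]
        stop("duplicate (participant, biomarker, draw_date) rows in ", path,
             ": ", paste(utils::head(paste0(
                 offenders$participant_id, "/", offenders$biomarker, "/",
                 offenders$draw_date), 6L), collapse = "; "))
    }
    p <- if (!is.null(participants_path)) readParticipants(participants_path)
         else NULL
    tab <- measurementTable(m, p)
    attr(tab@measurements, "rejected") <- rejected
    tab
}

#' Read a participants CSV
#'
#' @param path CSV with columns `participant_id,sex,age_years` and optional
#'   `bmi_baseline,bmi_followup`.
#' @return data.frame in the canonical participant layout.
#' @export
readParticipants <- function(path) {
    if (!file.exists(path))
        stop("participants file does not exist: ", path)
    p <- read.csv(path, stringsAsFactors = FALSE)
    if (!"participant_id" %in% names(p))
        stop("participants CSV is missing required column: participant_id")
    p$participant_id <- as.character(p$participant_id)
    if ("sex" %in% names(p)) {
        p$sex <- tolower(as.character(p$sex))
        p$sex[p$sex %in% c("", "na", "unknown")] <- NA_character_
    }
    p
}

#' Read an intervention-choice CSV
#'
#' @param path CSV with columns `participant_id,intervention_id`; one row per
#'   chosen intervention.
#' @return data.frame of unique (participant, intervention) pairs.
#' @export
readInterventions <- function(path) {
    if (!file.exists(path))
        stop("interventions file does not exist: ", path)
    ch <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("participant_id", "intervention_id")
    missing_cols <- setdiff(need, names(ch))
    if (length(missing_cols))
        stop("interventions CSV is missing required column(s): ",
             paste(missing_cols, collapse = ", "))
    ch$participant_id <- as.character(ch$participant_id)
    ch$intervention_id <- as.character(ch$intervention_id)
    if (anyDuplicated(ch[need]))
        stop("duplicate (participant_id, intervention_id) pairs in ", path)
    ch[need]
}

#' Write cohort tables to CSV
#'
#' Inverse of [readMeasurements()]: writes the measurement table (ISO-8601
#' dates) and, optionally, the participant table, so that reading the files
#' back reproduces the object.
#'
#' @param table a \linkS4class{MeasurementTable}.
#' @param path output path for the measurements CSV.
#' @param participants_path optional output path for the participants CSV.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(table, path, participants_path = NULL) {
    stopifnot(is(table, "MeasurementTable"))
    m <- table@measurements
    m$draw_date <- format(m$draw_date, "%Y-%m-%d")
    write.csv(m, path, row.names = FALSE, quote = FALSE)
    if (!is.null(participants_path))
        write.csv(table@participants, participants_path,
                  row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Extract baseline / follow-up pairs
#'
#' For every (participant, biomarker) with at least two measurements, selects
#' the earliest measurement as baseline and a follow-up measurement at least
#' `min_gap_days` later (strictly after baseline). With
#' `strategy = "earliest"` (default) the first qualifying follow-up is used;
#' with `"latest"` the last. Participants or biomarkers with no qualifying
#' follow-up are omitted.
#'
#' @param table a \linkS4class{MeasurementTable}.
#' @param min_gap_days minimum whole-day gap between baseline and follow-up
#'   (default 30).
#' @param strategy `"earliest"` or `"latest"` qualifying follow-up.
#' @return data.frame with columns `participant_id`, `biomarker`,
#'   `baseline_value`, `followup_value`, `baseline_date`, `followup_date`,
#'   `delta` (= followup - baseline), ordered by participant then biomarker.
#' @export
extractPairs <- function(table, min_gap_days = 30,
                         strategy = c("earliest", "latest")) {
    stopifnot(is(table, "MeasurementTable"), min_gap_days >= 0)
    strategy <- match.arg(strategy)
    m <- table@measurements
    if (!nrow(m)) return(.emptyPairs())
    m <- m[order(m$participant_id, m$biomarker, m$draw_date), , drop = FALSE]
    key <- paste(m$participant_id, m$biomarker, sep = "\r")
    gid <- match(key, unique(key))
    first <- !duplicated(gid)
    base_date <- m$draw_date[first][gid]
    base_value <- m$value[first][gid]
    qualifies <- m$draw_date > base_date &
        as.numeric(m$draw_date - base_date) >= min_gap_days
    idx <- which(qualifies)
    if (!length(idx)) return(.emptyPairs())
    g <- gid[idx]
    sel <- if (strategy == "earliest") !duplicated(g)
           else !duplicated(g, fromLast = TRUE)
    fu <- idx[sel]
    out <- data.frame(
        participant_id = m$participant_id[fu],
        biomarker = m$biomarker[fu],
        baseline_value = base_value[fu],
        followup_value = m$value[fu],
        baseline_date = base_date[fu],
        followup_date = m$draw_date[fu],
        stringsAsFactors = FALSE)
    out$delta <- out$followup_value - out$baseline_value
    out <- out[order(out$participant_id, out$biomarker), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyPairs <- function() {
    data.frame(participant_id = character(), biomarker = character(),
               baseline_value = numeric(), followup_value = numeric(),
               baseline_date = as.Date(character()),
               followup_date = as.Date(character()),
               delta = numeric(), stringsAsFactors = FALSE)
}

#' Load clinical range rules
#'
#' Reads a YAML (or JSON) configuration of per-biomarker direction-of-risk
#' thresholds into a \linkS4class{RangeRuleSet}. The package ships a default
#' configuration of 17 common blood biomarkers with Quest-style reference
#' thresholds (e.g. vitamin D `<30`, LDL `>130`, ALT `>46` male / `>29`
#' female); `loadRangeRules()` with no argument loads it.
#'
#' Schema, per biomarker key: `direction` (`high` = risk above threshold,
#' `low` = risk below), `threshold` (single number, or mapping with `male`
#' and `female`), `units` (carried opaquely, never converted), optional
#' `sex_stratified` (logical, analyse separately by sex).
#'
#' @param path path to the YAML/JSON rules file; `NULL` for the bundled
#'   default.
#' @return A `RangeRuleSet`.
#' @export
loadRangeRules <- function(path = NULL) {
    if (is.null(path))
        path <- system.file("extdata", "range_rules.yaml",
                            package = "biodelta", mustWork = TRUE)
    cfg <- yaml::read_yaml(path)
    rows <- lapply(names(cfg), function(bm) {
        spec <- cfg[[bm]]
        if (is.null(spec$direction) ||
            !spec$direction %in% c("high", "low"))
            stop("range rule config error at '", bm, "$direction': ",
                 "expected 'high' or 'low', got '", spec$direction, "'")
        thr <- spec$threshold
        if (is.list(thr)) {
            tm <- thr$male; tf <- thr$female
        } else {
            tm <- thr; tf <- thr
        }
        if (!is.numeric(tm) || !is.numeric(tf) ||
            length(tm) != 1L || length(tf) != 1L || !is.finite(tm) ||
            !is.finite(tf))
            stop("range rule config error at '", bm, "$threshold': ",
                 "threshold(s) must be single finite numbers")
        data.frame(biomarker = bm, direction = spec$direction,
                   threshold_male = tm, threshold_female = tf,
                   units = if (is.null(spec$units)) "" else spec$units,
                   sex_stratified = isTRUE(spec$sex_stratified),
                   stringsAsFactors = FALSE)
    })
    rules <- do.call(rbind, rows)
    rownames(rules) <- NULL
    new("RangeRuleSet", rules = rules)
}
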