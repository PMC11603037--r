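#' Read raw cohort tables
#'
#' Long-format event tables carry one observation per row with the time offset
#' in minutes relative to the beginning of anesthesia induction (`T_begin` = 0;
#' preoperative events have negative offsets). Static tables carry one row per
#' surgery with one column per static feature. Nu-DESC tables carry recovery
#' room delirium screening assessments, five category scores of 0-2 points
#' each, timed in minutes after anesthesia end.
#'
#' Missing values are encoded as empty CSV fields; all files are UTF-8 with a
#' header row.
#'
#' @param path CSV file path.
#' @return A `data.frame` (events: columns `surgery_id, patient_id,
#'   feature_name, t_offset_min, value`; nudesc: `surgery_id, assess_time_min,
#'   c1..c5`).
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("surgery_id", "patient_id", "feature_name", "t_offset_min", "value")
  if (!all(need %in% names(ev))) {
    stop("events file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ev$t_offset_min))) stop("non-finite t_offset_min in events")
  ev
}

#' @rdname read_events
#' @export
read_statics <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("surgery_id", "patient_id") %in% names(st))) {
    stop("statics file must have surgery_id and patient_id columns")
  }
  st
}

#' @rdname read_events
#' @export
read_nudesc <- function(path) {
  nu <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("surgery_id", "assess_time_min", paste0("c", 1:5))
  if (!all(need %in% names(nu))) {
    stop("nudesc file must have columns: ", paste(need, collapse = ", "))
  }
  validate_nudesc(nu)
  nu
}

validate_nudesc <- function(nudesc) {
  sc <- as.matrix(nudesc[, paste0("c", 1:5)])
  if (any(is.na(sc)) || any(sc < 0L) || any(sc > 2L) || any(sc != round(sc))) {
    stop("Nu-DESC category points must be integers in {0, 1, 2}")
  }
  invisible(TRUE)
}

#' Label surgeries for postoperative delirium from Nu-DESC assessments
#'
#' The Nu-DESC total score is the sum of the five category points (0-10). A
#' surgery is labelled POD positive (`Y = 1`) if at least one of its recovery
#' room assessments has a total score of 1 or more, and negative (`Y = 0`) if
#' every assessment scored zero in all categories. Surgeries without any
#' assessment cannot be labelled: they are excluded from the output (not
#' labelled 0) and recorded in the `exclusions` attribute.
#'
#' @param nudesc assessment table (`surgery_id, assess_time_min, c1..c5`).
#' @param surgeries surgery roster with columns `surgery_id, patient_id`; one
#'   row per surgery. Defines the cohort to be labelled.
#' @return `data.frame` with columns `surgery_id, patient_id, Y,
#'   n_assessments`, one row per assessed surgery, ordered as in `surgeries`.
#'   Attribute `exclusions`: character vector of surgery ids with no
#'   assessment.
#' @export
label_pod <- function(nudesc, surgeries) {
  validate_nudesc(nudesc)
  surgeries <- unique(surgeries[, c("surgery_id", "patient_id")])
  if (anyDuplicated(surgeries$surgery_id)) {
    stop("a surgery_id maps to more than one patient_id")
  }
  total <- rowSums(nudesc[, paste0("c", 1:5)])
  pos <- tapply(total, nudesc$surgery_id, function(s) any(s >= 1))
  n_ass <- tapply(total, nudesc$surgery_id, length)

  idx <- match(surgeries$surgery_id, names(pos))
  labelled <- !is.na(idx)
  out <- data.frame(
    surgery_id = surgeries$surgery_id[labelled],
    patient_id = surgeries$patient_id[labelled],
    Y = as.integer(pos[idx[labelled]]),
    n_assessments = as.integer(n_ass[idx[labelled]]),
    stringsAsFactors = FALSE
  )
  attr(out, "exclusions") <- surgeries$surgery_id[!labelled]
  out
}

#' Replace physiologically impossible values by missing
#'
#' Values outside a feature's declared valid range (bounds inclusive) are
#' replaced by `NA`; the number of event rows never changes. Features without a
#' declared range pass through untouched.
#'
#' @param events long-format event table.
#' @param specs `feature_spec` table covering every feature present in
#'   `events`.
#' @return list with `events` (cleaned table) and `removed` (named integer
#'   vector of out-of-range counts per feature).
#' @export
clean_valid_ranges <- function(events, specs) {
  unknown <- setdiff(unique(events$feature_name), specs$name)
  if (length(unknown) > 0) {
    stop("events reference undeclared feature(s): ",
         paste(unknown, collapse = ", "))
  }
  i <- match(events$feature_name, specs$name)
  lo <- specs$range_low[i]
  hi <- specs$range_high[i]
  bad <- !is.na(events$value) & !is.na(lo) & !is.na(hi) &
    (events$value < lo | events$value > hi)
  events$value[bad] <- NA_real_
  removed <- table(factor(events$feature_name[bad], levels = specs$name))
  list(events = events, removed = setNames(as.integer(removed), specs$name))
}

#' Retain features available for a minimum fraction of patients
#'
#' A feature is available for a patient if at least one of the patient's
#' surgeries has at least one non-missing value for it (event rows for dynamic
#' features, static columns for static ones). Features whose availability
#' fraction reaches `threshold` (inclusive) are retained.
#'
#' @param events long-format event table (dynamic features).
#' @param statics per-surgery static table (may be `NULL`).
#' @param patient_ids the full patient universe defining the denominator.
#' @param threshold availability fraction in `[0, 1]`; default 0.01.
#' @return character vector of retained feature names.
#' @export
filter_by_availability <- function(events, statics = NULL, patient_ids,
                                   threshold = 0.01) {
  if (length(patient_ids) == 0) stop("empty patient set")
  stopifnot(threshold >= 0, threshold <= 1)
  patient_ids <- unique(patient_ids)
  n_pat <- length(patient_ids)

  avail <- numeric(0)
  obs <- events[!is.na(events$value), c("patient_id", "feature_name")]
  if (nrow(obs) > 0) {
    per_feat <- tapply(obs$patient_id, obs$feature_name,
                       function(p) length(unique(p)))
    avail <- c(avail, per_feat / n_pat)
  }
  if (!is.null(statics)) {
    feat_cols <- setdiff(names(statics), c("surgery_id", "patient_id"))
    for (f in feat_cols) {
      pats <- unique(statics$patient_id[!is.na(statics[[f]])])
      avail[f] <- length(pats) / n_pat
    }
  }
  names(avail)[avail >= threshold]
}

#' Patient-level train/test split
#'
#' Patients (not surgeries) are randomly assigned to train or test, so that
#' all surgeries of a patient fall on the same side and no patient-level
#' information leaks across the split.
#'
#' @param labels labelled surgeries (`surgery_id, patient_id, Y`).
#' @param test_fraction fraction of patients assigned to the test side.
#' @param seed integer seed; the split is reproducible.
#' @return object of class `cohort_split`: list with `train_patient_ids`,
#'   `test_patient_ids`, `seed`.
#' @export
split_by_patient <- function(labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  patients <- sort(unique(labels$patient_id))
  if (length(patients) < 2) stop("need at least 2 patients to split")
  n_test <- max(1L, round(length(patients) * test_fraction))
  test_ids <- local_seed(seed, sample(patients, n_test))
  out <- list(
    train_patient_ids = setdiff(patients, test_ids),
    test_patient_ids = sort(test_ids),
    seed = as.integer(seed)
  )
  class(out) <- "cohort_split"
  out
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
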