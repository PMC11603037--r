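#' Feature specification tables
#'
#' A feature specification declares, for every clinical feature, its domain,
#' whether it is time-static or time-dynamic, its data type, the physiologically
#' valid value range used for cleaning, and the derived channels to build from
#' it (binary missingness indicator, cumulative dose, composite membership).
#'
#' @param name character vector of feature identifiers.
#' @param domain clinical domain label (e.g. "vital_signs", "inputs",
#'   "demographics", "medical_history").
#' @param time_variance "static" or "dynamic".
#' @param dtype "numeric" or "binary".
#' @param range_low,range_high valid physical range (inclusive); `NA` disables
#'   range cleaning for the feature.
#' @param missing_indicator logical; append a binary missingness-indicator
#'   channel for this feature.
#' @param cumulative logical; additionally build a running-sum channel
#'   (medication doses). Only meaningful for dynamic features.
#' @param composite_of for composite features, the member feature names as a
#'   single `;`-separated string (empty string otherwise).
#'
#' @return A `data.frame` of class `feature_spec` with one row per feature.
#' @export
feature_spec <- function(name, domain = "vital_signs",
                         time_variance = "dynamic", dtype = "numeric",
                         range_low = NA_real_, range_high = NA_real_,
                         missing_indicator = FALSE, cumulative = FALSE,
                         composite_of = "") {
  n <- length(name)
  spec <- data.frame(
    name = as.character(name),
    domain = rep_len(as.character(domain), n),
    time_variance = rep_len(as.character(time_variance), n),
    dtype = rep_len(as.character(dtype), n),
    range_low = rep_len(as.numeric(range_low), n),
    range_high = rep_len(as.numeric(range_high), n),
    missing_indicator = rep_len(as.logical(missing_indicator), n),
    cumulative = rep_len(as.logical(cumulative), n),
    composite_of = rep_len(as.character(composite_of), n),
    stringsAsFactors = FALSE
  )
  validate_feature_spec(spec)
}

validate_feature_spec <- function(spec) {
  stopifnot(is.data.frame(spec))
  required <- c("name", "domain", "time_variance", "dtype", "range_low",
                "range_high", "missing_indicator", "cumulative", "composite_of")
  missing_cols <- setdiff(required, names(spec))
  if (length(missing_cols) > 0) {
    stop("feature spec lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(spec$name)) {
    stop("duplicate feature names in spec: ",
         paste(unique(spec$name[duplicated(spec$name)]), collapse = ", "))
  }
  if (!all(spec$time_variance %in% c("static", "dynamic"))) {
    stop("time_variance must be 'static' or 'dynamic'")
  }
  if (!all(spec$dtype %in% c("numeric", "binary"))) {
    stop("dtype must be 'numeric' or 'binary'")
  }
  has_range <- !is.na(spec$range_low) & !is.na(spec$range_high)
  if (any(has_range & spec$range_low >= spec$range_high)) {
    bad <- spec$name[has_range & spec$range_low >= spec$range_high]
    stop("valid_range low must be < high for: ", paste(bad, collapse = ", "))
  }
  if (any(spec$cumulative & spec$time_variance != "dynamic")) {
    stop("cumulative features must be dynamic: ",
         paste(spec$name[spec$cumulative & spec$time_variance != "dynamic"],
               collapse = ", "))
  }
  members <- composite_members(spec)
  for (f in names(members)) {
    for (m in members[[f]]) {
      i <- match(m, spec$name)
      if (is.na(i)) stop("composite '", f, "' references unknown member '", m, "'")
      if (spec$time_variance[i] != "dynamic") {
        stop("composite '", f, "' member '", m, "' must be dynamic")
      }
    }
  }
  class(spec) <- unique(c("feature_spec", class(spec)))
  spec
}

#' @rdname feature_spec
#' @param spec a `feature_spec` table.
#' @return `composite_members()`: named list mapping each composite feature to
#'   its member feature names.
#' @export
composite_members <- function(spec) {
  idx <- which(nzchar(spec$composite_of))
  out <- lapply(idx, function(i) {
    trimws(strsplit(spec$composite_of[i], ";", fixed = TRUE)[[1]])
  })
  names(out) <- spec$name[idx]
  out
}

#' Read / write feature specifications as CSV
#'
#' Columns: `name,domain,time_variance,dtype,range_low,range_high,`
#' `missing_indicator,cumulative,composite_of`. Missing range bounds are empty
#' fields; composite members are `;`-separated.
#'
#' @param path file path.
#' @return `read_feature_specs()` returns a validated `feature_spec` table.
#' @export
read_feature_specs <- function(path) {
  spec <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(composite_of = "character"))
  spec$missing_indicator <- as.logical(spec$missing_indicator)
  spec$cumulative <- as.logical(spec$cumulative)
  spec$composite_of[is.na(spec$composite_of)] <- ""
  validate_feature_spec(spec)
}

#' @rdname read_feature_specs
#' @param spec a `feature_spec` table.
#' @export
write_feature_specs <- function(spec, path) {
  utils::write.csv(as.data.frame(spec), path, row.names = FALSE, na = "")
  invisible(path)
}
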