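# Shared fixtures and small oracles, built in code at test time.

toy_events <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(surgery_id = r[[1]], patient_id = r[[2]], feature_name = r[[3]],
               t_offset_min = as.numeric(r[[4]]), value = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

toy_surgeries <- function(ids, t_end = 120, patient = NULL) {
  data.frame(surgery_id = ids,
             patient_id = if (is.null(patient)) paste0("pat_", ids) else patient,
             t_end = rep_len(t_end, length(ids)),
             stringsAsFactors = FALSE)
}

toy_nudesc <- function(surgery_id, cats, t = 30) {
  data.frame(surgery_id = surgery_id, assess_time_min = t,
             c1 = cats[1], c2 = cats[2], c3 = cats[3], c4 = cats[4],
             c5 = cats[5], stringsAsFactors = FALSE)
}

# tensor with fully specified values/mask for rule-table tests
toy_tensor <- function(values, mask = NULL, channels = NULL, interval = 3) {
  if (is.null(mask)) mask <- ifelse(is.na(values), 1, 0)
  if (length(dim(values)) == 2) {
    values <- array(values, c(1, dim(values)))
    mask <- array(mask, dim(values))
  }
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(values)[2]))
  seq_tensor(values, mask, channels,
             paste0("s", seq_len(dim(values)[1])), interval)
}

# brute-force AUROC: enumerate all positive/negative pairs, ties count 1/2
auroc_brute <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# a small cached null cohort used by several suites
null_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(n_patients = 120,
                                           surgery_length_range = c(45, 90),
                                           surgery_length_meanlog = log(60)),
                                seed = 400)
    }
    cache
  }
})
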