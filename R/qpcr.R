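# Delta-Ct / delta-delta-Ct quantification for paired tumor/normal qPCR.

#' Read a qPCR Ct table
#'
#' CSV with columns `patient_id`, `tissue` (`tumor`/`normal`), `target`
#' (e.g. `gag`, `env`), `ct_target`, `ct_reference` (reference gene Ct,
#' e.g. RPL32). Technical replicates (repeated rows per patient, tissue and
#' target) are averaged. Rows with a missing or non-positive Ct are
#' excluded and counted in `attr(x, "n_dropped")`.
#'
#' @param path Path to the CSV.
#' @return A `data.frame` of measurements, one row per (patient, tissue,
#'   target).
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tissue", "target", "ct_target", "ct_reference")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop("qPCR table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(m$tissue %in% c("tumor", "normal"))) {
    stop("tissue must be 'tumor' or 'normal'")
  }
  m$ct_target <- num_or_na(m$ct_target)
  m$ct_reference <- num_or_na(m$ct_reference)
  ok <- is.finite(m$ct_target) & is.finite(m$ct_reference) &
    m$ct_target > 0 & m$ct_reference > 0
  n_dropped <- sum(!ok)
  m <- m[ok, , drop = FALSE]
  agg <- stats::aggregate(m[c("ct_target", "ct_reference")],
                          by = m[c("patient_id", "tissue", "target")],
                          FUN = mean)
  agg <- agg[order(agg$target, agg$patient_id, agg$tissue), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "n_dropped") <- n_dropped
  agg
}

#' Delta-Ct of a measurement
#'
#' `ct_target - ct_reference`: the cycle-threshold difference between the
#' target and the reference gene (lower values mean higher expression).
#'
#' @param ct_target,ct_reference Numeric Ct vectors.
#' @return Numeric vector of delta-Ct values.
#' @export
delta_ct <- function(ct_target, ct_reference) {
  ct_target - ct_reference
}

#' Per-patient delta-delta-Ct and fold change
#'
#' Matches each patient's tumor and normal measurements per target and
#' computes `ddct = dCt_tumor - dCt_normal` and the relative expression
#' `fc = 2^-ddct`. Every patient must contribute exactly one tumor and one
#' normal measurement per target; unmatched patients raise an error listing
#' their ids.
#'
#' @param measurements Measurement table from [read_qpcr()].
#' @return A `data.frame` with `target`, `patient_id`, `delta_ct_tumor`,
#'   `delta_ct_normal`, `ddct`, `fc`, `log2fc` (`== -ddct`).
#' @export
qpcr_fold_change <- function(measurements) {
  measurements$dct <- delta_ct(measurements$ct_target,
                               measurements$ct_reference)
  out <- lapply(split(measurements, measurements$target), function(m) {
    tum <- m[m$tissue == "tumor", ]
    nor <- m[m$tissue == "normal", ]
    unmatched <- union(setdiff(tum$patient_id, nor$patient_id),
                       setdiff(nor$patient_id, tum$patient_id))
    if (length(unmatched)) {
      stop("unpaired qPCR measurements for target '", m$target[1L],
           "', patient(s): ", paste(sort(unmatched), collapse = ", "))
    }
    nor <- nor[match(tum$patient_id, nor$patient_id), ]
    ddct <- tum$dct - nor$dct
    data.frame(target = tum$target, patient_id = tum$patient_id,
               delta_ct_tumor = tum$dct, delta_ct_normal = nor$dct,
               ddct = ddct, fc = 2^(-ddct), log2fc = -ddct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarize delta-delta-Ct results per target
#'
#' Mean and sample SD (n - 1) of the per-patient delta-delta-Ct, the mean
#' and median of the per-patient fold changes, and, since averaging
#' fold changes and exponentiating the mean delta-delta-Ct differ (Jensen's
#' inequality for the convex map `2^-x`), also `fc_from_mean_ddct =
#' 2^-mean(ddct)`. The per-patient log2 fold changes (`-ddct`) are returned
#' for bar-chart export.
#'
#' @param fc Per-patient table from [qpcr_fold_change()].
#' @return A list with a per-target `summary` data frame (`target`,
#'   `n_pairs`, `mean_ddct`, `sd_ddct` — `NA` for a single pair —,
#'   `mean_fc`, `median_fc`, `fc_from_mean_ddct`) and the `per_patient`
#'   table.
#' @export
qpcr_summarize <- function(fc) {
  rows <- lapply(split(fc, fc$target), function(f) {
    data.frame(target = f$target[1L], n_pairs = nrow(f),
               mean_ddct = mean(f$ddct),
               sd_ddct = if (nrow(f) > 1L) sd(f$ddct) else NA_real_,
               mean_fc = mean(f$fc), median_fc = median(f$fc),
               fc_from_mean_ddct = 2^(-mean(f$ddct)),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary,
       per_patient = fc[c("target", "patient_id", "log2fc")])
}
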