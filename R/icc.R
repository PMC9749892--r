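# ROI fluorescence quantification: background normalization and pooled
# per-ZT averaging.

#' Normalize ROI intensities to brain background
#'
#' Each neuron's mean intensity is divided by the background fluorescence of
#' its own brain.  The ratio convention (rather than subtraction) makes the
#' normalized value dimensionless and comparable across imaging sessions; it
#' is also scale-invariant: rescaling a brain's intensities and background
#' together leaves the normalized values unchanged.
#'
#' @param table an ROI data.frame (see [validate_roi_table()]).
#' @return the table with a `normalized_intensity` column appended.
#' @export
normalize_roi <- function(table) {
  table <- validate_roi_table(table)
  table$normalized_intensity <- table$mean_intensity / table$background_intensity
  table
}

#' Per-ZT fluorescence profile
#'
#' Mean +/- SEM of normalized intensity per Zeitgeber time point, pooling
#' all neurons from all brains (the neuron is the unit).  With
#' `per_brain = TRUE`, per-brain means are computed first and averaged
#' across brains instead.  ZT points absent from the data are omitted and
#' flagged.
#'
#' @param table a normalized ROI table ([normalize_roi()] output); rows are
#'   filtered to `genotype` and `channel` when given.
#' @param genotype,channel optional filters.
#' @param per_brain average per-brain means instead of pooling neurons.
#' @return An object of class `fluorescence_summary`: data.frame with `zt`,
#'   `n`, `mean`, `sem`, plus attributes `argmax_zt` (ZT of the peak mean)
#'   and `missing_zt` (measured ZT points with no data).
#' @export
zt_profile <- function(table, genotype = NULL, channel = NULL,
                       per_brain = FALSE) {
  if (is.null(table$normalized_intensity))
    stop("table has no normalized_intensity; run normalize_roi() first",
         call. = FALSE)
  if (!is.null(genotype)) table <- table[table$genotype == genotype, ]
  if (!is.null(channel)) table <- table[table$channel == channel, ]
  if (nrow(table) == 0) stop("no rows after filtering", call. = FALSE)
  prof <- do.call(rbind, lapply(sort(unique(table$zt)), function(z) {
    rows <- table[table$zt == z, ]
    vals <- if (per_brain) {
      vapply(split(rows$normalized_intensity, rows$brain_id), mean, numeric(1))
    } else {
      rows$normalized_intensity
    }
    data.frame(zt = z, n = length(vals), mean = mean(vals), sem = sem(vals))
  }))
  missing <- setdiff(ROI_ZTS, prof$zt)
  if (length(missing))
    warning(sprintf("no data at ZT %s", paste(missing, collapse = ", ")),
            call. = FALSE)
  structure(prof, class = c("fluorescence_summary", "data.frame"),
            argmax_zt = prof$zt[which.max(prof$mean)],
            missing_zt = missing)
}
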