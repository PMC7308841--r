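#' Extracted phenotype record
#'
#' Holds the morphometric trait set of one plant: plant height `PH` and
#' per-branch insertion heights `BH` (cm), basal/half-plant/apical stem
#' diameters `BD`, `HD`, `AD` (mm), per-branch inclination `BI` (degrees,
#' 0--180 from the zenith), per-leaf inclination `LI` (degrees, 0--90) and
#' per-leaf area `LA` (cm^2). Missing values are explicit `NA`s; the reasons
#' are kept in the `missing_log` attribute (a data.frame with columns
#' `trait`, `organ_index`, `reason`) and feed the Sw weighting adjustment.
#'
#' @param plant_id character id of the plant.
#' @param PH plant height, cm (scalar, `NA` if missing).
#' @param BH numeric vector of branch insertion heights, cm.
#' @param BD,HD,AD basal, half-plant and apical stem diameter, mm.
#' @param BI numeric vector of branch inclinations, degrees.
#' @param LI numeric vector of leaf inclinations, degrees.
#' @param LA numeric vector of leaf areas, cm^2.
#' @param missing_log optional data.frame of missing-value events.
#' @return object of class `trait_record`.
#' @export
trait_record <- function(plant_id = "plant", PH = NA_real_,
                         BH = numeric(0), BD = NA_real_, HD = NA_real_,
                         AD = NA_real_, BI = numeric(0), LI = numeric(0),
                         LA = numeric(0), missing_log = NULL) {
  chk_nonneg <- function(x, nm) {
    if (any(!is.na(x) & x < 0)) stop("'", nm, "' must be non-negative")
  }
  for (nm in c("PH", "BH", "BD", "HD", "AD", "LA"))
    chk_nonneg(get(nm), nm)
  if (any(!is.na(LI) & (LI < 0 | LI > 90)))
    stop("'LI' must lie in [0, 90] degrees")
  if (any(!is.na(BI) & (BI < 0 | BI > 180)))
    stop("'BI' must lie in [0, 180] degrees")
  rec <- structure(list(plant_id = as.character(plant_id),
                        PH = as.numeric(PH), BH = as.numeric(BH),
                        BD = as.numeric(BD), HD = as.numeric(HD),
                        AD = as.numeric(AD), BI = as.numeric(BI),
                        LI = as.numeric(LI), LA = as.numeric(LA)),
                   class = "trait_record")
  attr(rec, "missing_log") <- missing_log %||%
    data.frame(trait = character(0), organ_index = integer(0),
               reason = character(0))
  rec
}

trait_units <- c(PH = "cm", BH = "cm", BD = "mm", HD = "mm", AD = "mm",
                 BI = "deg", LI = "deg", LA = "cm2")

#' Flatten a trait record to long format
#'
#' @param x a [trait_record()].
#' @param row.names,optional,... ignored, present for S3 compatibility.
#' @return data.frame with columns `plant_id`, `trait`, `organ_index`
#'   (0 for whole-plant traits), `value` and `unit`.
#' @export
as.data.frame.trait_record <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- list(
    data.frame(trait = "PH", organ_index = 0L, value = x$PH),
    if (length(x$BH)) data.frame(trait = "BH", organ_index = seq_along(x$BH),
                                 value = x$BH),
    data.frame(trait = c("BD", "HD", "AD"), organ_index = 0L,
               value = c(x$BD, x$HD, x$AD)),
    if (length(x$BI)) data.frame(trait = "BI", organ_index = seq_along(x$BI),
                                 value = x$BI),
    if (length(x$LI)) data.frame(trait = "LI", organ_index = seq_along(x$LI),
                                 value = x$LI),
    if (length(x$LA)) data.frame(trait = "LA", organ_index = seq_along(x$LA),
                                 value = x$LA))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$plant_id <- x$plant_id
  out$unit <- unname(trait_units[out$trait])
  out[, c("plant_id", "trait", "organ_index", "value", "unit")]
}

#' @export
print.trait_record <- function(x, ...) {
  fmt <- function(v) if (length(v) == 0) "-" else
    paste(ifelse(is.na(v), "NA", sprintf("%.2f", v)), collapse = ", ")
  cat(sprintf("<trait_record '%s'>\n", x$plant_id))
  cat(sprintf("  PH  (cm) : %s\n", fmt(x$PH)))
  cat(sprintf("  BH  (cm) : %s\n", fmt(x$BH)))
  cat(sprintf("  D   (mm) : BD %s | HD %s | AD %s\n", fmt(x$BD), fmt(x$HD),
              fmt(x$AD)))
  cat(sprintf("  BI (deg) : %s\n", fmt(x$BI)))
  cat(sprintf("  LI (deg) : %s\n", fmt(x$LI)))
  cat(sprintf("  LA (cm2) : %s\n", fmt(x$LA)))
  ml <- attr(x, "missing_log")
  if (!is.null(ml) && nrow(ml))
    cat(sprintf("  %d missing value(s): %s\n", nrow(ml),
                paste(unique(ml$trait), collapse = ", ")))
  invisible(x)
}

## Rebuild a trait_record from a long-format data.frame (inverse of
## as.data.frame.trait_record); used by read_traits().
df_to_trait_record <- function(df) {
  pick <- function(tr) {
    d <- df[df$trait == tr, , drop = FALSE]
    d <- d[order(d$organ_index), , drop = FALSE]
    d$value
  }
  scalar <- function(tr) {
    v <- pick(tr)
    if (length(v) == 0) NA_real_ else v[1]
  }
  trait_record(plant_id = df$plant_id[1], PH = scalar("PH"), BH = pick("BH"),
               BD = scalar("BD"), HD = scalar("HD"), AD = scalar("AD"),
               BI = pick("BI"), LI = pick("LI"), LA = pick("LA"))
}
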