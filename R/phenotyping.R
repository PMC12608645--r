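#' @title Metabolic phenotype classifiers and landscape analysis
#' @description Classification of cells by pyruvate-flux partitioning
#'   (fermentation r12 vs respiration r18), by net lactate transport
#'   direction (Warburg / reverse-Warburg / fermentation state), population
#'   censuses, and the LDH-PDH metabolic landscape with attractor
#'   detection.
#' @name phenotyping-module
NULL

MSX_LABELS <- c("FERM_PP", "FERM_P_RESP_M", "RESP_P_FERM_M", "RESP_PP",
                "DEAD")
MSX_STATUSES <- c("WARBURG", "REVERSE_WARBURG", "FERMENTATION_STATE",
                  "NONE", "DEAD")

#' Classify the fermentation/respiration phenotype
#'
#' Cells are predominantly fermentative when the LDH flux exceeds the PDH
#' flux (`r12 > r18`), with pronounced fermentation when `r12 > 10 r18`
#' (more than 90% of pyruvate to lactate); symmetrically for respiration.
#' A negative `r12` (lactate consumed toward pyruvate) counts as zero
#' fermentation here - that reverse flux is captured by the
#' reverse-Warburg status instead. Ties fall to the respiratory hybrid.
#'
#' @param r12 LDH flux (mM/min), interval average; may be negative.
#' @param r18 PDH flux (mM/min), non-negative.
#' @return Factor with levels FERM_PP, FERM_P_RESP_M, RESP_P_FERM_M,
#'   RESP_PP (vectorized).
#' @export
classify_phenotype <- function(r12, r18) {
  if (any(!is.finite(r12)) || any(!is.finite(r18)))
    stop("non-finite flux in phenotype classification")
  f <- pmax(r12, 0)
  lab <- ifelse(f > 10 * r18, "FERM_PP",
         ifelse(r18 > 10 * f, "RESP_PP",
         ifelse(f > r18, "FERM_P_RESP_M", "RESP_P_FERM_M")))
  factor(lab, levels = MSX_LABELS)
}

#' Classify the lactate (Warburg) status
#'
#' The Warburg effect is net lactate excretion; the reverse-Warburg effect
#' is net uptake. Within a neutral band `eps` around zero the cell is in
#' the fermentation state when its phenotype is fermentative (lactate
#' produced but equilibrated, not excreted), otherwise NONE.
#'
#' @param net_mct Net MCT flux (mM/min, positive = export).
#' @param label Phenotype labels from [classify_phenotype()].
#' @param eps Neutral band (mM/min), >= 0; see [warburg_eps()].
#' @return Factor with levels WARBURG, REVERSE_WARBURG,
#'   FERMENTATION_STATE, NONE (vectorized).
#' @export
classify_lactate_status <- function(net_mct, label, eps = 1e-6) {
  if (any(eps < 0)) stop("eps must be non-negative")
  ferm <- label %in% c("FERM_PP", "FERM_P_RESP_M")
  st <- ifelse(net_mct > eps, "WARBURG",
        ifelse(net_mct < -eps, "REVERSE_WARBURG",
        ifelse(ferm, "FERMENTATION_STATE", "NONE")))
  factor(st, levels = MSX_STATUSES)
}

#' Adaptive neutral band for the Warburg classification
#'
#' Default band: 1% of the median absolute net MCT flux over the living
#' population at the evaluation instant, floored at 1e-6 mM/min.
#'
#' @param net_mct Net MCT fluxes of the living cells.
#' @return A single non-negative number.
#' @export
warburg_eps <- function(net_mct) {
  if (!length(net_mct)) return(1e-6)
  max(1e-6, 0.01 * stats::median(abs(net_mct)))
}

#' Population fractions and state counts
#'
#' Fractions of each phenotype label and lactate status over the living
#' population (each partition sums to one), plus counts of cells by state
#' (proliferative, quiescent, necrotic, debris).
#'
#' @param labels Phenotype labels (living cells).
#' @param statuses Lactate statuses (living cells).
#' @param phases Phase names of all agents (see [cell_phases()]).
#' @return List with `label_fractions`, `status_fractions`, `counts`, and
#'   `empty` (TRUE when no living cells - fractions are then NA).
#' @export
population_fractions <- function(labels, statuses, phases = character()) {
  n <- length(labels)
  empty <- n == 0
  lf <- if (empty) stats::setNames(rep(NA_real_, 4), MSX_LABELS[1:4])
        else table(factor(labels, levels = MSX_LABELS[1:4])) / n
  sf <- if (empty) stats::setNames(rep(NA_real_, 4), MSX_STATUSES[1:4])
        else table(factor(statuses, levels = MSX_STATUSES[1:4])) / n
  counts <- c(
    proliferative = sum(phases %in% c("G1", "S", "G2", "M")),
    quiescent = sum(phases == "G0"),
    necrotic = sum(phases %in% c("NECROTIC_SWELLING", "NECROTIC_SHRINKING")),
    debris = sum(phases == "DEBRIS"))
  list(label_fractions = c(lf), status_fractions = c(sf), counts = counts,
       empty = empty)
}

#' LDH-PDH landscape histogram
#'
#' Two-dimensional histogram of living cells in the space spanned by LDH
#' and PDH gene expression - the projection in which the oxidative,
#' glycolytic and intermediate attractors separate.
#'
#' @param ldh,pdh Expression values of living cells.
#' @param bins Number of bins per axis.
#' @param ldh_range,pdh_range Axis ranges (values outside are clamped into
#'   the edge bins).
#' @return Object of class `msx_landscape`: counts matrix plus bin
#'   midpoints.
#' @export
landscape_density <- function(ldh, pdh, bins = 60, ldh_range = c(0, 6),
                              pdh_range = c(0, 1.4)) {
  stopifnot(length(ldh) == length(pdh))
  if (length(ldh) && (any(!is.finite(ldh)) || any(!is.finite(pdh))))
    stop("non-finite expression values")
  bx <- seq(ldh_range[1], ldh_range[2], length.out = bins + 1)
  by <- seq(pdh_range[1], pdh_range[2], length.out = bins + 1)
  ix <- pmin(pmax(findInterval(ldh, bx, all.inside = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(pdh, by, all.inside = TRUE), 1), bins)
  m <- matrix(0L, bins, bins)
  if (length(ix)) {
    t <- table(factor(ix, levels = 1:bins), factor(iy, levels = 1:bins))
    m <- matrix(as.integer(t), bins, bins)
  }
  structure(list(counts = m,
                 ldh_mid = (bx[-1] + bx[-length(bx)]) / 2,
                 pdh_mid = (by[-1] + by[-length(by)]) / 2),
            class = "msx_landscape")
}

#' Accumulate landscape frames
#'
#' Element-wise sum of two landscape histograms (time integration of cell
#' metabolic states).
#'
#' @param a,b `msx_landscape` objects on identical bins.
#' @return The accumulated `msx_landscape`.
#' @export
landscape_accumulate <- function(a, b) {
  stopifnot(identical(dim(a$counts), dim(b$counts)))
  a$counts <- a$counts + b$counts
  a
}

#' Detect attractors in a landscape
#'
#' Local maxima of the (lightly smoothed) density histogram above a
#' prominence threshold, reported as (LDH, PDH) coordinates - the
#' high-density basins of the metabolic landscape.
#'
#' @param landscape An `msx_landscape`.
#' @param prominence Minimum peak density as a fraction of the maximum.
#' @param min_separation Minimum distance between attractors, in bins.
#' @return data.frame with `ldh`, `pdh`, `density`, ordered by density.
#' @export
find_attractors <- function(landscape, prominence = 0.1,
                            min_separation = 5) {
  m <- landscape$counts
  n <- nrow(m)
  # 3x3 box smoothing
  pad <- matrix(0, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- m
  sm <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2)
    sm <- sm + pad[di + 1:n, dj + 1:n]
  sm <- sm / 9
  thr <- prominence * max(sm)
  peaks <- NULL
  for (i in 1:n) for (j in 1:n) {
    v <- sm[i, j]
    if (v < thr || v == 0) next
    nb <- sm[max(1, i - 1):min(n, i + 1), max(1, j - 1):min(n, j + 1)]
    if (v >= max(nb)) peaks <- rbind(peaks, c(i, j, v))
  }
  if (is.null(peaks))
    return(data.frame(ldh = numeric(), pdh = numeric(), density = numeric()))
  peaks <- peaks[order(-peaks[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (k in seq_len(nrow(peaks))) {
    if (!keep[k]) next
    if (k < nrow(peaks)) {
      for (l in (k + 1):nrow(peaks)) {
        if (keep[l] && sqrt(sum((peaks[k, 1:2] - peaks[l, 1:2])^2)) <
            min_separation)
          keep[l] <- FALSE
      }
    }
  }
  peaks <- peaks[keep, , drop = FALSE]
  data.frame(ldh = landscape$ldh_mid[peaks[, 1]],
             pdh = landscape$pdh_mid[peaks[, 2]],
             density = peaks[, 3])
}
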