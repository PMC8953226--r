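## Intracellular metabolite panels: energy and redox charges, AxP
## cross-method normalization, min-max scaling, Euclidean distances,
## classical (Torgerson) multidimensional scaling and relaxation
## metrics of the embedded time trajectory.

#' Adenylate energy charge
#'
#' AEC = (ATP + 0.5 ADP) / (ATP + ADP + AMP), a 0..1 index of the
#' cellular energy status (about 0.9 in growing yeast).
#'
#' @param atp,adp,amp pool sizes, umol/gDMB (vectors allowed).
#' @return numeric AEC in \[0, 1\].
#' @export
#' @examples
#' energy_charge(1, 0, 0)   # 1
#' energy_charge(1, 1, 1)   # 0.5
energy_charge <- function(atp, adp, amp) {
  if (any(c(atp, adp, amp) < 0)) stop("pool sizes must be >= 0")
  tot <- atp + adp + amp
  if (any(tot <= 0)) stop("total adenylate pool must be positive")
  (atp + 0.5 * adp) / tot
}

#' Catabolic and anabolic reduction charges
#'
#' Catabolic charge = NADH / (NADH + NAD+); anabolic charge =
#' NADPH / (NADPH + NADP+). Also returns the couple totals and the
#' reduced/oxidized ratios.
#'
#' @param nadh,nad,nadph,nadp pool sizes, umol/gDMB.
#' @return list with `catabolic_charge`, `anabolic_charge`,
#'   `total_nad_couple`, `total_nadp_couple`, `ratio_nadh_nad`,
#'   `ratio_nadph_nadp`.
#' @export
reduction_charges <- function(nadh, nad, nadph, nadp) {
  if (any(c(nadh, nad, nadph, nadp) < 0))
    stop("pool sizes must be >= 0")
  if (any(nadh + nad <= 0) || any(nadph + nadp <= 0))
    stop("each redox couple must have a positive total pool")
  list(catabolic_charge = nadh / (nadh + nad),
       anabolic_charge = nadph / (nadph + nadp),
       total_nad_couple = nadh + nad,
       total_nadp_couple = nadph + nadp,
       ratio_nadh_nad = nadh / nad,
       ratio_nadph_nadp = nadph / nadp)
}

#' Cross-method normalization of AxP concentrations
#'
#' Rescales HILIC-quantified adenylate pools to a reference method
#' using per-species factors (defaults from steady-state
#' cross-calibration: ATP 2.71, ADP 1.88, AMP 1.21).
#'
#' @param values named numeric vector or list of raw concentrations;
#'   names must be a subset of `names(factors)`.
#' @param factors named multiplicative factors.
#' @return corrected concentrations, same names.
#' @export
#' @examples
#' axp_normalize(c(ATP = 1, ADP = 1, AMP = 1))
axp_normalize <- function(values,
                          factors = c(ATP = 2.71, ADP = 1.88,
                                      AMP = 1.21)) {
  values <- unlist(values)
  if (any(values < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(values), names(factors))
  if (length(unknown))
    stop("no normalization factor for: ",
         paste(unknown, collapse = ", "))
  values * factors[names(values)]
}

#' Min-max normalize a samples x metabolites matrix
#'
#' Per-metabolite (column) scaling to \[0, 1\]:
#' (x - min) / (max - min) over the included sample set. Constant
#' columns map to 0 by convention.
#'
#' @param mat numeric matrix, samples in rows, metabolites in columns.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 samples")
  apply(mat, 2, function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  })
}

#' Euclidean distance matrix between samples
#'
#' @param mat numeric matrix, samples in rows (e.g. output of
#'   [minmax_normalize()]).
#' @return symmetric matrix of Euclidean distances, zero diagonal.
#' @export
metabolite_distances <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix contains missing values")
  as.matrix(stats::dist(mat, method = "euclidean"))
}

#' Classical (Torgerson) metric multidimensional scaling
#'
#' Double-centers the squared distance matrix, B = -1/2 J D^2 J with
#' J = I - 11'/n, eigendecomposes B, and returns the top-k
#' eigenvectors scaled by the square roots of their eigenvalues.
#' Axis signs are fixed deterministically: the first nonzero loading
#' of each axis is made positive. If fewer than `k` eigenvalues are
#' positive, fewer columns are returned with a warning.
#'
#' @param distances square symmetric distance matrix, zero diagonal.
#' @param k target embedding dimension (default 2).
#' @return list of class `mds_result` with `coordinates`
#'   (samples x <= k, column means zero), `eigenvalues` (descending,
#'   all of B), and `variance_fraction` (share of the positive
#'   eigenvalue mass captured per returned axis).
#' @export
classical_mds <- function(distances, k = 2) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(d))) > 1e-8) stop("diagonal must be zero")
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values[1], 0) * 1e-12 &
                 eg$values > 0)
  k_eff <- min(k, length(pos))
  if (k_eff < k)
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    length(pos), k_eff))
  if (k_eff == 0) stop("no positive eigenvalues; distances degenerate")
  coords <- eg$vectors[, seq_len(k_eff), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k_eff)]), k_eff)
  ## deterministic sign: first loading of noticeable size positive
  for (a in seq_len(k_eff)) {
    nz <- which(abs(coords[, a]) > 1e-10)
    if (length(nz) && coords[nz[1], a] < 0)
      coords[, a] <- -coords[, a]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("dim", seq_len(k_eff))
  structure(list(coordinates = coords,
                 eigenvalues = eg$values,
                 variance_fraction =
                   eg$values[seq_len(k_eff)] /
                     sum(pmax(eg$values, 0))),
            class = "mds_result")
}

#' Relaxation metrics of an embedded metabolome trajectory
#'
#' Distances in the MDS embedding from every sample to two anchor
#' samples: the pre-perturbation reference and the late-time attractor
#' the trajectory converges to. A convergence flag reports whether the
#' distance to the attractor decreases monotonically over a suffix of
#' the trajectory.
#'
#' @param mds an `mds_result` from [classical_mds()] with named rows.
#' @param reference_label,attractor_label row names of the two
#'   anchors.
#' @param convergence_from index (1-based) from which monotone
#'   convergence to the attractor is assessed; default 1.
#' @return data frame with `sample`, `dist_to_reference`,
#'   `dist_to_attractor`; attribute `converging` (logical).
#' @export
relaxation_metrics <- function(mds, reference_label, attractor_label,
                               convergence_from = 1) {
  co <- mds$coordinates
  labs <- rownames(co)
  if (!(reference_label %in% labs)) stop("reference label not found")
  if (!(attractor_label %in% labs)) stop("attractor label not found")
  dref <- sqrt(colSums((t(co) - co[reference_label, ])^2))
  datt <- sqrt(colSums((t(co) - co[attractor_label, ])^2))
  suffix <- datt[seq(convergence_from, length(datt))]
  conv <- all(diff(suffix) <= 1e-10)
  out <- data.frame(sample = labs, dist_to_reference = unname(dref),
                    dist_to_attractor = unname(datt),
                    stringsAsFactors = FALSE)
  attr(out, "converging") <- conv
  out
}

#' Collapse a tidy replicate panel to a samples x metabolites matrix
#'
#' Takes per-cell means over available replicates (replicate counts
#' may differ between series).
#'
#' @param panel data frame with columns `sample_time_min`,
#'   `metabolite`, `replicate`, `value_umol_gDMB`.
#' @param include optional character vector of metabolites to keep.
#' @return numeric matrix, rows named by sample time (sorted
#'   numerically), columns by metabolite.
#' @export
panel_to_matrix <- function(panel, include = NULL) {
  req <- c("sample_time_min", "metabolite", "replicate",
           "value_umol_gDMB")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    stop("panel lacks column(s): ", paste(miss, collapse = ", "))
  if (any(panel$value_umol_gDMB < 0))
    stop("concentrations must be >= 0")
  if (!is.null(include))
    panel <- panel[panel$metabolite %in% include, , drop = FALSE]
  agg <- stats::aggregate(value_umol_gDMB ~ sample_time_min + metabolite,
                          data = panel, FUN = mean)
  times <- sort(unique(agg$sample_time_min))
  mets <- sort(unique(agg$metabolite))
  m <- matrix(NA_real_, length(times), length(mets),
              dimnames = list(format(times, trim = TRUE), mets))
  m[cbind(match(agg$sample_time_min, times),
          match(agg$metabolite, mets))] <- agg$value_umol_gDMB
  m
}
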