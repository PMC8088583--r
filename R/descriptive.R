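#' Per-variable statistical moments
#'
#' Mean, variance, skewness and excess kurtosis for every degree of freedom
#' (position coordinate), plus per-atom aggregates used for threshold-based
#' atom selection. Variance uses the `n - 1` denominator; skew and kurtosis
#' use central moments over `n` (`skew = m3 / m2^1.5`,
#' `excess kurtosis = m4 / m2^2 - 3`). Zero-variance DOF get skew and
#' kurtosis 0 (flagged in `degenerate`) so downstream thresholding stays
#' total.
#'
#' @param ens a `coord_ensemble` or a features-by-frames matrix.
#' @return an object of class `moment_table`: list with `dof` (data.frame:
#'   dof, atom, axis, mean, variance, skew, kurtosis, degenerate) and `atom`
#'   (data.frame of per-atom maxima over the three DOF).
#' @export
variable_moments <- function(ens) {
  X <- if (inherits(ens, "coord_ensemble")) ens$X else as.matrix(ens)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 frames to compute moments")
  mu <- rowMeans(X)
  D <- X - mu
  m2 <- rowMeans(D^2)
  m3 <- rowMeans(D^3)
  m4 <- rowMeans(D^4)
  variance <- rowSums(D^2) / (n - 1)
  degenerate <- m2 <= 0
  skew <- ifelse(degenerate, 0, m3 / m2^1.5)
  kurt <- ifelse(degenerate, 0, m4 / m2^2 - 3)

  d <- nrow(X)
  is_coords <- inherits(ens, "coord_ensemble")
  atom_idx <- if (is_coords) rep(seq_len(d %/% 3L), each = 3L) else seq_len(d)
  axis <- if (is_coords) rep(c("x", "y", "z"), length.out = d) else
    rep("", d)
  dof_tab <- data.frame(dof = seq_len(d), atom = atom_idx, axis = axis,
                        mean = mu, variance = variance, skew = skew,
                        kurtosis = kurt, degenerate = degenerate)
  agg <- function(v) tapply(v, atom_idx, max)
  atom_tab <- data.frame(atom = sort(unique(atom_idx)),
                         variance = as.numeric(agg(variance)),
                         skew = as.numeric(agg(skew)),
                         kurtosis = as.numeric(agg(kurt)))
  if (is_coords) atom_tab$serial <- ens$atoms$serial
  structure(list(dof = dof_tab, atom = atom_tab), class = "moment_table")
}

#' @export
print.moment_table <- function(x, ...) {
  cat("<moment_table> ", nrow(x$dof), " DOF over ", nrow(x$atom), " atoms\n",
      sep = "")
  invisible(x)
}

#' Sampling adequacy: per-variable MSA and the KMO statistic
#'
#' The Kaiser-Meyer-Olkin statistic is the ratio of summed squared
#' off-diagonal correlations to that sum plus the summed squared off-diagonal
#' partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over `i != j`. The
#' per-variable Measure of Sampling Adequacy is the same ratio restricted to
#' row `i`. Both lie in `[0, 1]`; values near 1 indicate that variables share
#' common variance well captured by a factor/PC model.
#'
#' For a diagonal correlation matrix the ratio is 0/0; it is reported as 0
#' with a warning.
#'
#' @param R a correlation `stat_model` (or plain matrix with unit diagonal).
#' @param P a partial-correlation `stat_model` (or plain matrix) of the same
#'   dimension; its off-diagonal entries are the partial correlations.
#' @return list with `msa` (vector per DOF) and `kmo` (scalar).
#' @export
msa_kmo <- function(R, P) {
  Rm <- model_matrix(R)
  Pm <- model_matrix(P)
  if (!all(dim(Rm) == dim(Pm))) stop("R and P must have the same dimension")
  d <- nrow(Rm)
  off <- !diag(d)
  r2 <- Rm^2 * off
  q2 <- Pm^2 * off
  denom_i <- rowSums(r2) + rowSums(q2)
  msa <- ifelse(denom_i > 0, rowSums(r2) / denom_i, 0)
  denom <- sum(r2) + sum(q2)
  if (denom <= 0) {
    warning("degenerate input: no off-diagonal correlation; KMO reported as 0")
    kmo <- 0
  } else {
    kmo <- sum(r2) / denom
  }
  list(msa = msa, kmo = kmo)
}

#' Moment-threshold atom selection
#'
#' Keeps the atoms whose per-atom aggregate (max over the atom's three DOF)
#' meets or exceeds every supplied threshold; absent thresholds are ignored.
#' An empty selection is valid and warned about, never an error.
#'
#' @param moments a [variable_moments()] result.
#' @param variance_min,skew_min,kurtosis_min optional numeric thresholds.
#' @return integer vector of selected atom indices.
#' @export
threshold_select <- function(moments, variance_min = NULL, skew_min = NULL,
                             kurtosis_min = NULL) {
  if (!inherits(moments, "moment_table")) stop("expected a moment_table")
  at <- moments$atom
  keep <- rep(TRUE, nrow(at))
  if (!is.null(variance_min)) keep <- keep & at$variance >= variance_min
  if (!is.null(skew_min)) keep <- keep & at$skew >= skew_min
  if (!is.null(kurtosis_min)) keep <- keep & at$kurtosis >= kurtosis_min
  sel <- at$atom[keep]
  if (!length(sel)) warning("thresholds select no atoms")
  sel
}

#' Write a moment table as TSV
#' @param moments a `moment_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_moment_table <- function(moments, path) {
  utils::write.table(moments$dof, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
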