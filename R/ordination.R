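#' Canonical IUCN level-1 threat classes
#'
#' The 11 major direct-threat classes of the IUCN threat classification,
#' by their short names.
#' @return Character vector of length 11.
#' @export
threat_classes <- function() {
  c("Urbanization", "Agri- & aquaculture", "Energy production",
    "Transportation", "Harvesting/Hunting", "Intrusion",
    "Ecosystem changes", "Exotics & pathogens", "Pollution",
    "Geological events", "Climate change")
}

#' Validate a binary species-by-threat incidence matrix
#'
#' @param x Matrix or data.frame; rows = species (named), columns =
#'   threat classes; entries 0/1.
#' @param classes Expected column vocabulary; default [threat_classes()].
#'   Set to `NULL` to accept any column names.
#' @return A binary integer matrix with dimnames.
#' @export
validate_incidence <- function(x, classes = threat_classes()) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || any(!nzchar(rownames(x))))
    stop("incidence matrix must have species row names", call. = FALSE)
  rownames(x) <- trimws(rownames(x))
  if (anyDuplicated(rownames(x)))
    stop("duplicate species rows in incidence matrix", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("incidence entries must be 0/1", call. = FALSE)
  if (!is.null(classes)) {
    bad <- setdiff(colnames(x), classes)
    if (length(bad))
      stop("unknown threat classes: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  storage.mode(x) <- "integer"
  x
}

#' Read an incidence matrix from CSV
#'
#' First column = species labels; remaining columns = 0/1 incidences with
#' a header row of labels.
#' @param file CSV path.
#' @param classes Column vocabulary to validate against, or `NULL`.
#' @return Binary integer matrix.
#' @export
read_incidence <- function(file, classes = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  validate_incidence(m, classes = classes)
}

#' Write an incidence matrix to CSV
#' @param x Incidence matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_incidence <- function(x, file) {
  df <- data.frame(species = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

.new_ordination <- function(eigenvalues, row_coords, col_coords,
                            total_inertia, method) {
  frac <- if (total_inertia > 0) eigenvalues / total_inertia else
    rep(0, length(eigenvalues))
  structure(list(eigenvalues = eigenvalues,
                 axis_fractions = frac,
                 row_coords = row_coords,
                 col_coords = col_coords,
                 total_inertia = total_inertia,
                 method = method),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, "ordination: total inertia", format(x$total_inertia, digits = 6),
      "\naxis fractions:", paste(sprintf("%.1f%%", 100 * x$axis_fractions),
                                 collapse = ", "), "\n")
  invisible(x)
}

# deterministic axis orientation: largest-magnitude row loading positive
.orient_axes <- function(row_coords, col_coords) {
  for (k in seq_len(ncol(row_coords))) {
    v <- row_coords[, k]
    if (v[which.max(abs(v))] < 0) {
      row_coords[, k] <- -row_coords[, k]
      if (!is.null(col_coords)) col_coords[, k] <- -col_coords[, k]
    }
  }
  list(row = row_coords, col = col_coords)
}

#' Double principal coordinate analysis of threats on a phylogeny
#'
#' Places the species affected by at least one threat by principal
#' coordinates of their (transformed) patristic distances, then places
#' each threat type at the weighted centroid of the species it affects,
#' and extracts the principal axes of the threat centroids. Threats are
#' weighted proportionally to the number of species they affect, so rare
#' threats do not dominate. The axis fractions refer to the
#' between-threat (centroid) inertia, i.e. the share of phylogenetic
#' differences among species affected by different threat types.
#'
#' @param threats Binary species-by-threat matrix (see
#'   [validate_incidence()]).
#' @param distances Patristic distance matrix over (at least) the species
#'   in `threats`.
#' @param transform Distance transform applied before embedding:
#'   `"sqrt"` (default; square-rooted tree metrics are Euclidean),
#'   `"cailliez"` (additive constant correction) or `"none"`.
#' @param tol Eigenvalue tolerance for rank decisions.
#' @return An `ordination` with `row_coords` = threat centroid
#'   coordinates, `col_coords` = species coordinates on the same axes,
#'   eigenvalues = per-axis between-threat inertia.
#' @export
dpcoa <- function(threats, distances, transform = c("sqrt", "cailliez", "none"),
                  tol = 1e-10) {
  transform <- match.arg(transform)
  threats <- validate_incidence(threats, classes = NULL)
  affected <- rownames(threats)[rowSums(threats) > 0L]
  if (length(affected) < 2L)
    stop("need at least 2 species affected by at least one threat",
         call. = FALSE)
  missing <- setdiff(affected, rownames(distances))
  if (length(missing))
    stop("species missing from distance matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  X <- threats[affected, , drop = FALSE]
  empty <- colSums(X) == 0L
  if (any(empty)) {
    warning("dropping empty threat column(s): ",
            paste(colnames(X)[empty], collapse = ", "), call. = FALSE)
    X <- X[, !empty, drop = FALSE]
  }
  D <- as.matrix(distances)[affected, affected]
  D <- switch(transform,
              sqrt = sqrt(D),
              cailliez = .cailliez(D),
              none = D)

  n_t <- colSums(X)
  w_threat <- n_t / sum(n_t)                       # threat weights
  Pmat <- sweep(X, 2L, n_t, "/")                   # species profile per threat
  p_sp <- as.numeric(Pmat %*% w_threat)            # mixture species weights

  # weighted principal coordinates of D
  A <- -0.5 * D^2
  Ac <- sweep(A, 1L, as.numeric(A %*% p_sp))            # A (I - p 1')
  Ac <- sweep(Ac, 2L, as.numeric(crossprod(Ac, p_sp)))  # (I - 1 p') . .
  s <- sqrt(p_sp)
  M <- Ac * (s %o% s)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) < -max(tol, 1e-8) * max(abs(ev$values), 1))
    stop("distances are not Euclidean-embeddable after the '", transform,
         "' transform; try transform = \"sqrt\" or \"cailliez\"",
         call. = FALSE)
  keep <- ev$values > tol * max(ev$values, 1)
  L <- ev$values[keep]
  S_coords <- sweep(ev$vectors[, keep, drop = FALSE] / s, 2L, sqrt(L), "*")
  rownames(S_coords) <- affected

  # threat centroids in the species PCoA space
  C <- t(Pmat) %*% S_coords
  # principal axes of weighted centroids (weighted by w_threat; centroid
  # cloud is centered at the origin by construction)
  B <- crossprod(C * sqrt(w_threat))
  evB <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep2 <- evB$values > tol * max(evB$values, 1)
  axes <- evB$vectors[, keep2, drop = FALSE]
  eigv <- evB$values[keep2]
  threat_coords <- C %*% axes
  species_coords <- S_coords %*% axes
  if (ncol(threat_coords) > 0L)
    colnames(threat_coords) <- colnames(species_coords) <-
      paste0("axis", seq_len(ncol(threat_coords)))
  o <- .orient_axes(threat_coords, species_coords)
  out <- .new_ordination(eigv, o$row, o$col, sum(eigv), "DPCoA")
  out$species_weights <- stats::setNames(p_sp, affected)
  out$threat_weights <- stats::setNames(w_threat, colnames(X))
  out$species_inertia <- sum(L)
  out
}

# Cailliez additive correction: smallest c so that d + c is Euclidean
.cailliez <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  W1 <- -0.5 * J %*% D^2 %*% J
  W2 <- -0.5 * J %*% D %*% J
  B <- rbind(cbind(matrix(0, n, n), 2 * W1),
             cbind(-diag(n), -4 * W2))
  cc <- max(Re(eigen(B, only.values = TRUE)$values))
  Dc <- D + cc
  diag(Dc) <- 0
  Dc
}

#' Correspondence analysis of a contingency table
#'
#' Chi-square standardized residuals are decomposed by SVD; rows and
#' columns are returned in principal coordinates. The total inertia equals
#' the Pearson chi-square statistic divided by the grand total.
#'
#' @param tab Nonnegative contingency matrix (e.g. threats x areas).
#' @param tol Singular-value tolerance.
#' @return An `ordination` with `row_coords` and `col_coords` in principal
#'   coordinates.
#' @export
correspondence_analysis <- function(tab, tol = 1e-12) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("contingency table must be nonnegative", call. = FALSE)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero row(s)/column(s): ",
            paste(c(rownames(tab)[zr], colnames(tab)[zc]), collapse = ", "),
            call. = FALSE)
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  N <- sum(tab)
  if (N <= 0) stop("contingency table has zero grand total", call. = FALSE)
  P <- tab / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - r %o% cc) / sqrt(r %o% cc)
  sv <- svd(S)
  keep <- sv$d > tol * max(sv$d, 1)
  if (!any(keep)) {
    # perfect independence: zero-inertia result, not an error
    rc <- matrix(0, nrow(tab), 0, dimnames = list(rownames(tab), NULL))
    ccoord <- matrix(0, ncol(tab), 0, dimnames = list(colnames(tab), NULL))
    return(.new_ordination(numeric(0), rc, ccoord, 0, "CA"))
  }
  d <- sv$d[keep]
  rowc <- sweep(sv$u[, keep, drop = FALSE] / sqrt(r), 2L, d, "*")
  colc <- sweep(sv$v[, keep, drop = FALSE] / sqrt(cc), 2L, d, "*")
  dimnames(rowc) <- list(rownames(tab), paste0("axis", seq_along(d)))
  dimnames(colc) <- list(colnames(tab), paste0("axis", seq_along(d)))
  o <- .orient_axes(rowc, colc)
  .new_ordination(d^2, o$row, o$col, sum(sv$d^2), "CA")
}

#' Cross-tabulate threats against geographic areas or habitats
#'
#' Cell (t, a) counts the species affected by threat t that carry label a;
#' a species present in several areas/habitats is counted once per label.
#'
#' @param threats Binary species-by-threat matrix.
#' @param labels Binary species-by-label matrix (areas or habitats).
#' @return Integer contingency matrix, threats as rows.
#' @export
build_threat_by_label_table <- function(threats, labels) {
  threats <- validate_incidence(threats, classes = NULL)
  labels <- validate_incidence(labels, classes = NULL)
  common <- intersect(rownames(threats), rownames(labels))
  if (!length(common))
    stop("no shared species between threat and label matrices", call. = FALSE)
  t(threats[common, , drop = FALSE]) %*% labels[common, , drop = FALSE]
}

#' Write ordination coordinates to CSV files and an eigen-summary to JSON
#'
#' @param x An `ordination`.
#' @param prefix Path prefix; writes `<prefix>_rows.csv`,
#'   `<prefix>_cols.csv` and `<prefix>_eigen.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_ordination <- function(x, prefix) {
  f1 <- paste0(prefix, "_rows.csv")
  f2 <- paste0(prefix, "_cols.csv")
  f3 <- paste0(prefix, "_eigen.json")
  utils::write.csv(data.frame(label = rownames(x$row_coords), x$row_coords,
                              check.names = FALSE), f1, row.names = FALSE)
  utils::write.csv(data.frame(label = rownames(x$col_coords), x$col_coords,
                              check.names = FALSE), f2, row.names = FALSE)
  jsonlite::write_json(list(method = x$method,
                            eigenvalues = x$eigenvalues,
                            axis_fractions = x$axis_fractions,
                            total_inertia = x$total_inertia),
                       f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}
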