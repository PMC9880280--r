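# Structural connectomes: loading (TVB connectivity-zip dialect or plain
# CSV), weight normalization, delays, row-wise shuffling nulls, and a
# synthetic two-hemisphere generator so everything runs without downloads.

#' Construct and validate a connectome
#'
#' @param weights n x n non-negative coupling weights, `weights[j, k]` is
#'   the strength of the connection from region j to region k. The diagonal
#'   is stored as written but treated as 1 (self-coupling) by the brain
#'   simulator.
#' @param tract_lengths n x n symmetric non-negative tract lengths, mm.
#' @param centres optional n x 3 region centre coordinates, mm.
#' @param labels optional region labels (defaults to `region_1` ...).
#' @param volumes optional gray-matter volumes (positive).
#' @param hemisphere optional per-region tags (e.g. `"L"`/`"R"`).
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, tract_lengths, centres = NULL,
                       labels = NULL, volumes = NULL, hemisphere = NULL) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (!all(dim(tract_lengths) == c(n, n)))
    stop("tract_lengths shape does not match weights")
  if (any(weights < 0)) stop("negative weights")
  if (any(tract_lengths < 0)) stop("negative tract lengths")
  if (max(abs(tract_lengths - t(tract_lengths))) > 1e-6)
    stop("tract_lengths must be symmetric")
  if (!is.null(centres)) {
    centres <- as.matrix(centres)
    if (!all(dim(centres) == c(n, 3)) || any(!is.finite(centres)))
      stop("centres must be a finite n x 3 matrix")
  }
  if (!is.null(volumes) && (length(volumes) != n || any(volumes <= 0)))
    stop("volumes must be positive, one per region")
  labels <- labels %||% paste0("region_", seq_len(n))
  structure(list(n_regions = n, weights = unname(weights),
                 tract_lengths = unname(tract_lengths), centres = centres,
                 labels = as.character(labels), volumes = volumes,
                 hemisphere = hemisphere),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, %d nonzero weights (density %.2f)\n",
              x$n_regions, sum(x$weights > 0),
              sum(x$weights > 0) / (x$n_regions * (x$n_regions - 1))))
  if (!is.null(x$centres)) cat("  centres available (delays derivable)\n")
  invisible(x)
}

read_num_matrix <- function(path, sep = "") {
  nf <- utils::count.fields(path, sep = sep, blank.lines.skip = TRUE)
  if (length(unique(nf)) != 1)
    stop(sprintf("ragged matrix in %s: row %d has %d fields, expected %d",
                 basename(path), which(nf != nf[1])[1],
                 nf[which(nf != nf[1])[1]], nf[1]))
  as.matrix(read.table(path, header = FALSE, sep = sep))
}

#' Load a structural connectome
#'
#' Supports the TVB connectivity dialect -- a zip file or directory holding
#' `weights.txt`, `tract_lengths.txt` and `centres.txt` (label x y z per
#' row), all whitespace-separated -- and a plain-CSV dialect
#' (`weights.csv`, `tract_lengths.csv`, optional `centres.csv`).
#'
#' @param path zip file or directory.
#' @param dialect `"auto"`, `"tvb-zip"` or `"csv"`.
#' @return A [connectome()] object. When centres are absent, delays are
#'   unavailable and `$centres` is NULL.
#' @export
load_connectome <- function(path, dialect = c("auto", "tvb-zip", "csv")) {
  dialect <- match.arg(dialect)
  dir <- path
  if (file.exists(path) && !dir.exists(path) && grepl("\\.zip$", path)) {
    dir <- tempfile("conn")
    utils::unzip(path, exdir = dir)
    inner <- list.dirs(dir, recursive = FALSE)
    if (!file.exists(file.path(dir, "weights.txt")) && length(inner) == 1)
      dir <- inner
  }
  if (dialect == "auto")
    dialect <- if (file.exists(file.path(dir, "weights.txt"))) "tvb-zip"
               else "csv"
  if (dialect == "tvb-zip") {
    w <- read_num_matrix(file.path(dir, "weights.txt"))
    tl <- read_num_matrix(file.path(dir, "tract_lengths.txt"))
    centres <- NULL; labels <- NULL
    cpath <- file.path(dir, "centres.txt")
    if (file.exists(cpath)) {
      cdf <- read.table(cpath, header = FALSE)
      labels <- as.character(cdf[[1]])
      centres <- as.matrix(cdf[, 2:4])
    }
    connectome(w, tl, centres = centres, labels = labels)
  } else {
    w <- read_num_matrix(file.path(dir, "weights.csv"), sep = ",")
    tl <- read_num_matrix(file.path(dir, "tract_lengths.csv"), sep = ",")
    centres <- NULL; labels <- NULL
    cpath <- file.path(dir, "centres.csv")
    if (file.exists(cpath)) {
      cdf <- read.table(cpath, header = FALSE, sep = ",")
      labels <- as.character(cdf[[1]])
      centres <- as.matrix(cdf[, 2:4])
    }
    connectome(w, tl, centres = centres, labels = labels)
  }
}

#' Write a connectome as plain CSV files
#' @param conn a [connectome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectome_csv <- function(conn, dir) {
  stopifnot(inherits(conn, "connectome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(conn$weights, file.path(dir, "weights.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(conn$tract_lengths, file.path(dir, "tract_lengths.csv"),
              sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(conn$centres))
    write.table(data.frame(conn$labels, conn$centres),
                file.path(dir, "centres.csv"), sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Normalize fiber counts into coupling weights
#'
#' Divides the fiber count of each region pair by the sum of the two
#' regions' gray-matter volumes, then rescales globally so the maximum
#' weight is 1 (the coupling strength S then carries all magnitude).
#'
#' @param fiber_counts n x n non-negative matrix.
#' @param volumes positive gray-matter volumes, length n.
#' @param rescale rescale max to 1 (default TRUE; skipped if all zero).
#' @return weight matrix.
#' @examples
#' normalize_weights(matrix(100, 1, 1), volumes = 10, rescale = FALSE) # 5
#' @export
normalize_weights <- function(fiber_counts, volumes, rescale = TRUE) {
  f <- as.matrix(fiber_counts)
  if (any(volumes <= 0)) stop("volumes must be positive")
  if (any(f < 0)) stop("fiber counts must be non-negative")
  w <- f / outer(volumes, volumes, `+`)
  if (rescale && max(w) > 0) w <- w / max(w)
  w
}

#' Axonal propagation delays from tract lengths
#'
#' @param conn a [connectome()].
#' @param v_c axonal propagation speed, mm/ms (default 3).
#' @return delay matrix, ms, with zero diagonal.
#' @export
compute_delays <- function(conn, v_c = 3) {
  stopifnot(inherits(conn, "connectome"))
  if (v_c <= 0) stop("v_c must be positive")
  d <- conn$tract_lengths / v_c
  diag(d) <- 0
  d
}

#' Row-wise weight shuffle (structure-destroying null connectome)
#'
#' For each region in turn, its outgoing off-diagonal weights are randomly
#' permuted. The per-row weight multiset and the global weight distribution
#' are preserved; tract lengths (hence delays) are not modified.
#'
#' @param conn a [connectome()].
#' @param seed integer seed.
#' @return a new [connectome()].
#' @export
shuffle_weights <- function(conn, seed = 1) {
  stopifnot(inherits(conn, "connectome"))
  if (conn$n_regions < 2) stop("need at least 2 regions")
  set.seed(seed)
  w <- conn$weights
  n <- conn$n_regions
  for (j in seq_len(n)) {
    off <- setdiff(seq_len(n), j)
    w[j, off] <- w[j, sample(off)]
  }
  out <- conn
  out$weights <- w
  out
}

#' Generate a synthetic two-hemisphere connectome
#'
#' A stand-in for an empirical DTI connectome: region centres are sampled
#' inside two mirrored ellipsoids (one per hemisphere), tract lengths are
#' inter-centre Euclidean distances times a tortuosity factor, and weights
#' are log-normal, decay exponentially with distance, and are denser within
#' than between hemispheres. Deterministic for a given seed.
#'
#' @param n_regions even region count (>= 4).
#' @param seed integer seed.
#' @param tortuosity tract-length inflation over the Euclidean distance.
#' @param lambda_mm weight distance-decay length, mm.
#' @param inter_scale multiplicative attenuation of inter-hemisphere
#'   weights.
#' @param sdlog log-normal weight spread (heavy tail).
#' @return a [connectome()] with centres, labels, volumes and hemisphere
#'   tags; weights rescaled to max 1.
#' @export
generate_synthetic_connectome <- function(n_regions = 68, seed = 1,
                                          tortuosity = 1.3, lambda_mm = 60,
                                          inter_scale = 0.5, sdlog = 1) {
  if (n_regions < 4) stop("n_regions must be >= 4")
  if (n_regions %% 2 != 0) stop("n_regions must be even (two hemispheres)")
  set.seed(seed)
  nh <- n_regions / 2
  # one hemisphere: ellipsoid centred at x = -32 mm, semi-axes 22/55/40 mm
  ax <- c(22, 55, 40); cx <- c(-32, 0, 10)
  pts <- matrix(NA_real_, nh, 3)
  i <- 0
  while (i < nh) {
    cand <- runif(3, -1, 1)
    if (sum(cand^2) <= 1) {
      i <- i + 1
      pts[i, ] <- cx + ax * cand
    }
  }
  centres <- rbind(pts, sweep(pts, 2, c(-1, 1, 1), `*`))  # mirror in x
  hemi <- rep(c("L", "R"), each = nh)
  labels <- c(sprintf("lh_region_%02d", seq_len(nh)),
              sprintf("rh_region_%02d", seq_len(nh)))
  d <- as.matrix(stats::dist(centres))
  tl <- d * tortuosity
  intra <- outer(hemi, hemi, `==`)
  w <- matrix(rlnorm(n_regions^2, meanlog = 0, sdlog = sdlog), n_regions)
  w <- w * exp(-d / lambda_mm) * ifelse(intra, 1, inter_scale)
  w <- (w + t(w)) / 2  # DTI weights are undirected
  diag(w) <- 0
  w <- w / max(w)
  volumes <- rlnorm(n_regions, meanlog = log(5000), sdlog = 0.4)
  connectome(w, tl, centres = centres, labels = labels, volumes = volumes,
             hemisphere = hemi)
}
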