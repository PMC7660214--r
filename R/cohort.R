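# Synthetic cohort generation and RSFC feature vectorization.
#
# A cohort holds, per subject: a symmetric r x r resting-state functional
# connectivity (RSFC) matrix with unit diagonal and entries in [-1, 1], a
# phenotype record (site, sex, age) and a binary diagnosis label
# (1 = patient, 0 = control).  The synthetic generator plants a
# class-dependent mean shift on a subset of lower-triangle connectivity
# features, adds per-site offsets and i.i.d. Gaussian noise, so that the
# subject-similarity graphs built downstream are smooth with respect to the
# diagnostic label -- the statistical structure the spectral analysis and
# the ensemble rely on.

#' Parameters for the synthetic cohort generator
#'
#' Defaults mirror the published ABIDE-derived cohort this model family is
#' usually run on: 403 patients and 468 controls scanned at 17 sites,
#' 111-region connectivity matrices, a male-dominated sex distribution
#' (727 of 871 subjects) and ages between 6 and 58 years.
#'
#' @param n_patients,n_controls Positive subject counts per class.
#' @param r Number of brain regions; the feature dimension is
#'   `d = r * (r - 1) / 2` lower-triangle entries.
#' @param effect_size Magnitude of the class-dependent mean shift: patients
#'   get `+effect_size / 2` and controls `-effect_size / 2` on the signal
#'   features (correlation units).
#' @param signal_fraction Fraction of the `d` features carrying the shift.
#' @param n_sites Number of acquisition sites (uniformly assigned).
#' @param site_effect Standard deviation of the per-site additive offset
#'   applied to every feature of subjects from that site.
#' @param sex_imbalance Probability that a subject is male.
#' @param age_range Length-2 numeric, `[min, max]` age in years; ages are
#'   uniform on this interval, independent of site.
#' @param noise_sd Standard deviation of the i.i.d. feature noise; must be
#'   positive.
#' @param seed Integer seed; identical parameters (seed included) reproduce
#'   bit-identical cohorts.
#'
#' @return An object of class `simulation_params`.
#' @seealso [generate_cohort()]
#' @export
simulation_params <- function(n_patients = 403L,
                              n_controls = 468L,
                              r = 111L,
                              effect_size = 0.5,
                              signal_fraction = 0.1,
                              n_sites = 17L,
                              site_effect = 0.1,
                              sex_imbalance = 727 / 871,
                              age_range = c(6, 58),
                              noise_sd = 0.2,
                              seed = 1L) {
  if (!is_count(n_patients) || !is_count(n_controls)) {
    stopf("n_patients and n_controls must be positive integers")
  }
  if (!is_count(r) || r < 2) stopf("r must be an integer >= 2")
  if (!is_count(n_sites)) stopf("n_sites must be a positive integer")
  if (!is_prob(signal_fraction)) stopf("signal_fraction must be in [0, 1]")
  if (!is_prob(sex_imbalance)) stopf("sex_imbalance must be in [0, 1]")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stopf("noise_sd must be a positive number")
  }
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      age_range[1] < 0 || age_range[2] < age_range[1]) {
    stopf("age_range must be [min, max] with 0 <= min <= max")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
      r = as.integer(r), effect_size = effect_size,
      signal_fraction = signal_fraction, n_sites = as.integer(n_sites),
      site_effect = site_effect, sex_imbalance = sex_imbalance,
      age_range = as.numeric(age_range), noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_params"
  )
}

#' Row-major lower-triangle feature order
#'
#' The fixed traversal used everywhere in the package to vectorize an
#' `r x r` symmetric matrix: strictly-below-diagonal pairs `(i, j)` with
#' `i > j`, ordered row-major -- `(2,1), (3,1), (3,2), (4,1), ...`.
#' This is the documented inverse mapping from feature index to matrix cell.
#'
#' @param r Number of regions.
#' @return A data frame with columns `feature` (1..d), `row`, `col`.
#' @export
lower_tri_map <- function(r) {
  if (!is_count(r) || r < 2) stopf("r must be an integer >= 2")
  row <- rep.int(2:r, times = 1:(r - 1L))
  col <- sequence(1:(r - 1L))
  data.frame(feature = seq_along(row), row = row, col = col)
}

#' Generate a seeded synthetic cohort
#'
#' Draws per-feature baseline connectivity levels, plants a symmetric
#' class-dependent mean shift of `effect_size` on a seeded random subset of
#' `signal_fraction * d` features, adds a per-site offset vector of scale
#' `site_effect` and i.i.d. `N(0, noise_sd^2)` noise, then rebuilds each
#' subject's RSFC matrix (symmetrized, clipped to `[-1, 1]`, unit diagonal).
#' Patients come first in subject order.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `cohort`: list with `subject_ids`, `rsfc`
#'   (named list of r x r matrices), `phenotypes` (data frame with columns
#'   `subject_id`, `site`, `sex`, `age`), `labels` (named 0/1 integer
#'   vector), `r`, and the generating `params`.
#' @examples
#' co <- generate_cohort(simulation_params(n_patients = 5, n_controls = 5,
#'                                         r = 8, seed = 42))
#' table(co$labels)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "simulation_params")) {
    params <- do.call(simulation_params, params)
  }
  p <- params
  n <- p$n_patients + p$n_controls
  d <- p$r * (p$r - 1L) / 2L
  map <- lower_tri_map(p$r)

  out <- with_seed(p$seed, {
    baseline <- stats::rnorm(d, mean = 0.2, sd = 0.15)
    n_signal <- ceiling(p$signal_fraction * d)
    signal_idx <- if (n_signal > 0) sample.int(d, n_signal) else integer(0)
    site_shift <- matrix(stats::rnorm(p$n_sites * d, sd = p$site_effect),
                         nrow = p$n_sites)
    labels <- c(rep(1L, p$n_patients), rep(0L, p$n_controls))
    site <- sample.int(p$n_sites, n, replace = TRUE)
    sex <- ifelse(stats::runif(n) < p$sex_imbalance, "M", "F")
    age <- stats::runif(n, p$age_range[1], p$age_range[2])

    x <- matrix(stats::rnorm(n * d, sd = p$noise_sd), nrow = n, ncol = d)
    x <- sweep(x, 2L, baseline, "+")
    if (n_signal > 0 && p$effect_size != 0) {
      shift <- ifelse(labels == 1L, p$effect_size / 2, -p$effect_size / 2)
      x[, signal_idx] <- x[, signal_idx] + shift
    }
    x <- x + site_shift[site, , drop = FALSE]
    x[x > 1] <- 1
    x[x < -1] <- -1
    list(x = x, labels = labels, site = site, sex = sex, age = age,
         signal_idx = sort(signal_idx))
  })

  ids <- sprintf("sub-%04d", seq_len(n))
  cell <- out$x
  rsfc <- vector("list", n)
  idx_lower <- cbind(map$row, map$col)
  idx_upper <- cbind(map$col, map$row)
  for (i in seq_len(n)) {
    m <- diag(1, p$r)
    m[idx_lower] <- cell[i, ]
    m[idx_upper] <- cell[i, ]
    rsfc[[i]] <- m
  }
  names(rsfc) <- ids
  labels <- out$labels
  names(labels) <- ids

  structure(
    list(
      subject_ids = ids,
      rsfc = rsfc,
      phenotypes = data.frame(
        subject_id = ids, site = out$site, sex = out$sex, age = out$age,
        stringsAsFactors = FALSE
      ),
      labels = labels,
      r = p$r,
      signal_features = out$signal_idx,
      params = p
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d subjects (%d patients / %d controls), %d regions, %d sites\n",
    length(x$subject_ids), sum(x$labels == 1L), sum(x$labels == 0L),
    x$r, length(unique(x$phenotypes$site))
  ))
  invisible(x)
}

#' Vectorize RSFC matrices into the n x d feature matrix
#'
#' Extracts each subject's strict lower triangle in the row-major order of
#' [lower_tri_map()], giving the `n x d` matrix of node features
#' (`d = r (r - 1) / 2`).
#'
#' @param cohort A `cohort` object (or a list of symmetric matrices).
#' @param tol Symmetry tolerance; matrices asymmetric beyond this are a
#'   data error.
#' @return An `n x d` numeric matrix with subjects as (named) rows and the
#'   feature order attached as attribute `"feature_order"`.
#' @export
vectorize_rsfc <- function(cohort, tol = 1e-8) {
  mats <- if (inherits(cohort, "cohort")) cohort$rsfc else cohort
  if (!length(mats)) stopf("no RSFC matrices supplied")
  r <- nrow(mats[[1]])
  map <- lower_tri_map(r)
  idx <- cbind(map$row, map$col)
  x <- matrix(NA_real_, nrow = length(mats), ncol = nrow(map))
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    if (nrow(m) != r || ncol(m) != r) stopf("subject %d: RSFC is not %d x %d", i, r, r)
    assert_symmetric(m, tol = tol, what = sprintf("RSFC matrix of subject %d", i))
    x[i, ] <- m[idx]
  }
  rownames(x) <- names(mats)
  attr(x, "feature_order") <- map
  x
}

#' Rebuild a symmetric matrix from a lower-triangle feature vector
#'
#' Inverse of [vectorize_rsfc()] for one subject: places the vector back in
#' the strict lower triangle (row-major order), mirrors it, and sets a unit
#' diagonal.
#'
#' @param x Numeric vector of length `r (r - 1) / 2`.
#' @param r Number of regions.
#' @return An `r x r` symmetric matrix with unit diagonal.
#' @export
rsfc_from_vector <- function(x, r) {
  map <- lower_tri_map(r)
  if (length(x) != nrow(map)) {
    stopf("expected %d features for r = %d, got %d", nrow(map), r, length(x))
  }
  m <- diag(1, r)
  m[cbind(map$row, map$col)] <- x
  m[cbind(map$col, map$row)] <- x
  m
}

#' Barbell fixture graph with a two-cluster signal
#'
#' Two complete clusters of `n_per_cluster` nodes joined by `bridge_edges`
#' unit-weight edges, plus the piecewise-constant signal that is `+1` on the
#' first cluster and `-1` on the second.  With zero bridges the graph has
#' two connected components and the signal lies entirely in the span of the
#' two zero-eigenvalue component indicators, which makes it the canonical
#' check that spectral energy concentrates where it must.
#'
#' @param n_per_cluster Cluster size, at least 2.
#' @param bridge_edges Number of distinct cross-cluster unit edges
#'   (row-major over cross pairs), `0 <= bridge_edges <= n_per_cluster^2`.
#' @return A list with `graph` (a `population_graph`) and `signal`.
#' @export
generate_barbell_fixture <- function(n_per_cluster, bridge_edges = 1L) {
  if (!is_count(n_per_cluster) || n_per_cluster < 2) {
    stopf("n_per_cluster must be an integer >= 2")
  }
  if (!is.numeric(bridge_edges) || bridge_edges < 0 ||
      bridge_edges != floor(bridge_edges)) {
    stopf("bridge_edges must be a non-negative integer")
  }
  if (bridge_edges > n_per_cluster^2) {
    stopf("at most %d bridge edges are possible", n_per_cluster^2)
  }
  n <- 2L * n_per_cluster
  w <- matrix(0, n, n)
  c1 <- seq_len(n_per_cluster)
  c2 <- n_per_cluster + c1
  w[c1, c1] <- 1
  w[c2, c2] <- 1
  diag(w) <- 0
  if (bridge_edges > 0) {
    pairs <- expand.grid(j = c2, i = c1)[, c("i", "j")]
    pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE][seq_len(bridge_edges), ]
    w[cbind(pairs$i, pairs$j)] <- 1
    w[cbind(pairs$j, pairs$i)] <- 1
  }
  ids <- sprintf("node-%02d", seq_len(n))
  dimnames(w) <- list(ids, ids)
  graph <- new_population_graph(w, config = list(kind = "fixture_barbell",
                                                 n_per_cluster = n_per_cluster,
                                                 bridge_edges = bridge_edges),
                                subject_ids = ids)
  list(graph = graph, signal = rep(c(1, -1), each = n_per_cluster))
}

#' Write / read a cohort as plain-text files
#'
#' Phenotypes and labels go to `<dir>/phenotypes.csv` (columns
#' `subject_id,site,sex,age,label`); each subject's RSFC matrix goes to
#' `<dir>/rsfc/<subject_id>.csv` (headerless dense CSV).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  rdir <- file.path(dir, "rsfc")
  dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phenotypes
  ph$label <- unname(cohort$labels[ph$subject_id])
  utils::write.csv(ph, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  for (id in cohort$subject_ids) {
    utils::write.table(cohort$rsfc[[id]], file.path(rdir, paste0(id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ph <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "site", "sex", "age", "label")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stopf("phenotypes.csv lacks columns: %s", paste(miss, collapse = ", "))
  ids <- as.character(ph$subject_id)
  rsfc <- lapply(ids, function(id) {
    m <- as.matrix(utils::read.csv(file.path(dir, "rsfc", paste0(id, ".csv")),
                                   header = FALSE))
    dimnames(m) <- NULL
    m
  })
  names(rsfc) <- ids
  labels <- as.integer(ph$label)
  names(labels) <- ids
  structure(
    list(
      subject_ids = ids,
      rsfc = rsfc,
      phenotypes = ph[, c("subject_id", "site", "sex", "age")],
      labels = labels,
      r = nrow(rsfc[[1]]),
      signal_features = integer(0),
      params = NULL
    ),
    class = "cohort"
  )
}

#' Inject graph-high-frequency noise into a feature matrix
#'
#' Adds noise confined to the top (high-eigenvalue) spectral modes of a
#' graph: `X + U_high Z`, with `Z` i.i.d. Gaussian.  Used to emulate
#' measurement noise that low-pass graph filtering should remove; on such
#' data classification is expected to peak at a filtering threshold
#' `k < n`.
#'
#' @param basis A `spectral_basis` (see [eigendecompose()]).
#' @param x `n x d` feature matrix.
#' @param fraction Fraction of the highest-frequency modes carrying noise.
#' @param scale Noise standard deviation per mode.
#' @param seed Integer seed.
#' @return The perturbed `n x d` matrix.
#' @export
add_highfrequency_noise <- function(basis, x, fraction = 0.5, scale = 1,
                                    seed = 1L) {
  stopifnot(inherits(basis, "spectral_basis"))
  n <- nrow(basis$vectors)
  if (nrow(x) != n) stopf("x must have %d rows", n)
  n_high <- max(1L, floor(fraction * n))
  hi <- (n - n_high + 1L):n
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_high * ncol(x), sd = scale), n_high, ncol(x))
    x + basis$vectors[, hi, drop = FALSE] %*% z
  })
}
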