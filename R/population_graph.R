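# Population-graph construction.
#
# Nodes are subjects; the edge weight between subjects i and j is
#
#   W(i, j) = sim(x_i, x_j) * sum_h 1[ M_h(v_i) = M_h(v_j) ]
#
# where sim is a Gaussian kernel of the correlation distance between the
# two subjects' lower-triangle RSFC vectors and M_h ranges over the
# selected categorical phenotypes (site, sex, binned age).  Dropping one
# factor or the other yields the RSFC-only and phenotype-only graph
# families; three reference baselines (fully connected, identity /
# disconnected, random binary) complete the set.

PHENOTYPE_ORDER <- c("site", "sex", "age")

#' Configuration of one population graph
#'
#' @param use_rsfc Use the RSFC similarity kernel factor?
#' @param phenotype_features Character subset of `c("site", "sex", "age")`
#'   (order-insensitive; stored canonically), possibly empty.
#' @param baseline_kind One of `"none"`, `"fc"`, `"identity"`, `"random"`.
#'   A baseline excludes both similarity factors.
#' @param age_bin_edges Ordered numeric bin edges used to discretize age
#'   when `"age"` is among the features; `NULL` means consecutive 5-year
#'   bins spanning the observed range.
#' @param sigma Kernel bandwidth for the RSFC similarity; `NULL` means the
#'   mean pairwise correlation distance of the cohort.
#' @param random_density Edge probability of the random baseline, in (0, 1].
#' @param seed Seed for the random baseline.
#' @return An object of class `graph_config` with a canonical `name`
#'   (e.g. `"sim_RSFC_site_sex"`).
#' @export
graph_config <- function(use_rsfc = FALSE,
                         phenotype_features = character(0),
                         baseline_kind = c("none", "fc", "identity", "random"),
                         age_bin_edges = NULL,
                         sigma = NULL,
                         random_density = 0.1,
                         seed = 1L) {
  baseline_kind <- match.arg(baseline_kind)
  phenotype_features <- as.character(phenotype_features)
  bad <- setdiff(phenotype_features, PHENOTYPE_ORDER)
  if (length(bad)) stopf("unknown phenotype features: %s", paste(bad, collapse = ", "))
  phenotype_features <- PHENOTYPE_ORDER[PHENOTYPE_ORDER %in% phenotype_features]
  if (baseline_kind != "none" && (use_rsfc || length(phenotype_features))) {
    stopf("a baseline graph excludes RSFC and phenotype similarity factors")
  }
  if (baseline_kind == "none" && !use_rsfc && !length(phenotype_features)) {
    stopf("empty graph definition: enable RSFC, phenotypes, or a baseline")
  }
  if (!is.numeric(random_density) || random_density <= 0 || random_density > 1) {
    stopf("random_density must be in (0, 1]")
  }
  if (!is.null(age_bin_edges) && is.unsorted(age_bin_edges, strictly = TRUE)) {
    stopf("age_bin_edges must be strictly increasing")
  }
  name <- if (baseline_kind != "none") {
    baseline_kind
  } else {
    paste(c("sim", if (use_rsfc) "RSFC", phenotype_features), collapse = "_")
  }
  structure(
    list(use_rsfc = use_rsfc, phenotype_features = phenotype_features,
         baseline_kind = baseline_kind, age_bin_edges = age_bin_edges,
         sigma = sigma, random_density = random_density,
         seed = as.integer(seed), name = name),
    class = "graph_config"
  )
}

#' @export
print.graph_config <- function(x, ...) {
  cat(sprintf("<graph_config> %s\n", x$name))
  invisible(x)
}

#' Population graph constructor (internal validation)
#' @noRd
new_population_graph <- function(weights, config, subject_ids) {
  assert_symmetric(weights, tol = 1e-10, what = "graph weight matrix")
  if (any(diag(weights) != 0)) stopf("graph diagonal must be exactly 0")
  if (any(weights < 0)) stopf("graph weights must be non-negative")
  dimnames(weights) <- list(subject_ids, subject_ids)
  structure(list(weights = weights, config = config, subject_ids = subject_ids),
            class = "population_graph")
}

#' @export
print.population_graph <- function(x, ...) {
  nm <- if (is.list(x$config)) x$config$name %||% x$config$kind else NULL
  w <- x$weights
  cat(sprintf("<population_graph> %s: %d nodes, %d nonzero edges\n",
              nm %||% "?", nrow(w), sum(w[upper.tri(w)] > 0)))
  invisible(x)
}

#' Gaussian kernel of the correlation distance between two feature vectors
#'
#' `exp(-rho^2 / (2 sigma^2))` with `rho = 1 - cor(xi, xj)` (Pearson).  A
#' constant vector has no defined correlation; by convention the similarity
#' is then 0 (no evidence of similarity), not an error.
#'
#' @param xi,xj Numeric vectors of equal length `>= 2`.
#' @param sigma Positive kernel bandwidth.
#' @return A similarity in `[0, 1]`, symmetric in its arguments.
#' @export
rsfc_similarity <- function(xi, xj, sigma) {
  if (length(xi) != length(xj) || length(xi) < 2) {
    stopf("xi and xj must share a length >= 2")
  }
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be positive")
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0) return(0)
  rho <- 1 - stats::cor(xi, xj)
  exp(-rho^2 / (2 * sigma^2))
}

#' Default age bins: consecutive 5-year intervals spanning the data
#' @noRd
default_age_bins <- function(ages, width = 5) {
  lo <- floor(min(ages) / width) * width
  hi <- ceiling((max(ages) + 1e-9) / width) * width
  if (hi <= lo) hi <- lo + width
  seq(lo, hi, by = width)
}

#' Discretize ages into categorical age groups
#' @noRd
bin_age <- function(ages, age_bin_edges = NULL) {
  edges <- age_bin_edges %||% default_age_bins(ages)
  as.integer(cut(ages, breaks = edges, right = FALSE, include.lowest = TRUE))
}

#' Number of matching categorical phenotypes between two subjects
#'
#' Counts `sum_h 1[M_h(vi) = M_h(vj)]` over the selected features; age is
#' compared after binning by `age_bin_edges`.  A missing (`NA`) value
#' matches nothing.
#'
#' @param vi,vj Lists or one-row data frames with entries `site`, `sex`,
#'   `age` (as needed).
#' @param features Non-empty character subset of `c("site", "sex", "age")`.
#' @param age_bin_edges Bin edges for age (required when `"age"` is used).
#' @return Integer in `0..length(features)`.
#' @export
phenotype_match_count <- function(vi, vj, features, age_bin_edges = NULL) {
  if (!length(features)) stopf("features must be non-empty")
  n_match <- 0L
  for (f in features) {
    a <- vi[[f]]
    b <- vj[[f]]
    if (f == "age") {
      if (is.null(age_bin_edges)) stopf("age comparison requires age_bin_edges")
      ab <- bin_age(c(a, b), age_bin_edges)
      a <- ab[1]
      b <- ab[2]
    }
    if (!is.na(a) && !is.na(b) && a == b) n_match <- n_match + 1L
  }
  n_match
}

#' Pairwise phenotype agreement matrix for one feature
#' @noRd
match_matrix <- function(v) {
  m <- outer(v, v, "==")
  m[is.na(m)] <- FALSE
  storage.mode(m) <- "double"
  m
}

#' Pairwise RSFC similarity matrix
#' @noRd
rsfc_similarity_matrix <- function(x, sigma = NULL) {
  sds <- apply(x, 1L, stats::sd)
  ok <- sds > 0
  rho <- matrix(NA_real_, nrow(x), nrow(x))
  if (sum(ok) >= 2) {
    rho[ok, ok] <- 1 - stats::cor(t(x[ok, , drop = FALSE]))
  }
  if (is.null(sigma)) {
    off <- rho[upper.tri(rho)]
    off <- off[is.finite(off)]
    sigma <- mean(off)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  s <- exp(-rho^2 / (2 * sigma^2))
  s[!is.finite(s)] <- 0
  s[!ok, ] <- 0
  s[, !ok] <- 0
  list(sim = s, sigma = sigma)
}

#' Build one population graph
#'
#' Applies the configured edge-weight function to every subject pair:
#' RSFC-only graphs use the correlation-distance kernel, phenotype-only
#' graphs the integer match count, combined graphs their product, and
#' baselines defer to [build_baseline_graph()].  The diagonal is zeroed.
#'
#' @param features `n x d` feature matrix from [vectorize_rsfc()] (ignored
#'   by phenotype-only and baseline configs).
#' @param cohort The `cohort` (phenotypes and subject ids).
#' @param config A [graph_config()].
#' @return A `population_graph` whose `config` records the realized
#'   `sigma` and `age_bin_edges`.
#' @export
build_population_graph <- function(features, cohort, config) {
  stopifnot(inherits(config, "graph_config"), inherits(cohort, "cohort"))
  n <- length(cohort$subject_ids)
  if (n < 2) stopf("need at least 2 subjects")
  if (config$baseline_kind != "none") {
    return(build_baseline_graph(config$baseline_kind, n,
                                density = config$random_density,
                                seed = config$seed,
                                subject_ids = cohort$subject_ids,
                                config = config))
  }
  w <- matrix(1, n, n)
  if (config$use_rsfc) {
    if (is.null(features) || nrow(features) != n) {
      stopf("features must be an n x d matrix aligned with the cohort")
    }
    sim <- rsfc_similarity_matrix(features, config$sigma)
    w <- w * sim$sim
    config$sigma <- sim$sigma
  }
  if (length(config$phenotype_features)) {
    cnt <- matrix(0, n, n)
    ph <- cohort$phenotypes
    for (f in config$phenotype_features) {
      v <- if (f == "age") {
        edges <- config$age_bin_edges %||% default_age_bins(ph$age)
        config$age_bin_edges <- edges
        bin_age(ph$age, edges)
      } else {
        ph[[f]]
      }
      cnt <- cnt + match_matrix(v)
    }
    w <- w * cnt
  }
  diag(w) <- 0
  w <- (w + t(w)) / 2   # remove rounding asymmetry
  new_population_graph(w, config, cohort$subject_ids)
}

#' Build a baseline population graph
#'
#' `fc`: every off-diagonal weight 1.  `identity`: the fully disconnected
#' graph -- the conventional identity adjacency reduces to no off-diagonal
#' edges once self-loops are dropped, so the stored weights are all zero
#' and its Laplacian vanishes.  `random`: symmetric binary edges, each
#' present independently with probability `density` (seeded).
#'
#' @param kind `"fc"`, `"identity"`, or `"random"`.
#' @param n Number of subjects, at least 2.
#' @param density Edge probability for `"random"`, in (0, 1].
#' @param seed Seed for `"random"`.
#' @param subject_ids Optional node names.
#' @param config Optional `graph_config` to attach.
#' @return A `population_graph`.
#' @export
build_baseline_graph <- function(kind, n, density = 0.1, seed = 1L,
                                 subject_ids = NULL, config = NULL) {
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  if (!kind %in% c("fc", "identity", "random")) {
    stopf("unknown baseline kind '%s'", kind)
  }
  subject_ids <- subject_ids %||% sprintf("sub-%04d", seq_len(n))
  w <- switch(kind,
    fc = matrix(1, n, n) - diag(1, n),
    identity = matrix(0, n, n),
    random = {
      if (density <= 0 || density > 1) stopf("density must be in (0, 1]")
      w <- matrix(0, n, n)
      up <- upper.tri(w)
      w[up] <- with_seed(seed, as.numeric(stats::runif(sum(up)) < density))
      w + t(w)
    }
  )
  config <- config %||% graph_config(baseline_kind = kind,
                                     random_density = density, seed = seed)
  new_population_graph(w, config, subject_ids)
}

#' Enumerate the standard family of graph configurations
#'
#' One RSFC-only graph, the seven phenotype-only graphs (all non-empty
#' subsets of site/sex/age), the seven RSFC-plus-phenotype graphs in the
#' same subset order, and optionally the three baselines.  The fixed order
#' is: `sim_RSFC`; subsets ordered by size then canonically
#' (site, sex, age, site_sex, site_age, sex_age, site_sex_age) for the
#' phenotype-only then RSFC-phenotype family; `fc`, `identity`, `random`.
#'
#' @param include_baselines Append the three baseline configs?
#' @param sigma,age_bin_edges,random_density,seed Passed to every
#'   [graph_config()].
#' @return A named list of `graph_config` objects (15 or 18).
#' @export
enumerate_graph_configs <- function(include_baselines = FALSE,
                                    sigma = NULL, age_bin_edges = NULL,
                                    random_density = 0.1, seed = 1L) {
  subsets <- list("site", "sex", "age",
                  c("site", "sex"), c("site", "age"), c("sex", "age"),
                  c("site", "sex", "age"))
  cfgs <- list(graph_config(use_rsfc = TRUE, sigma = sigma))
  for (s in subsets) {
    cfgs <- c(cfgs, list(graph_config(phenotype_features = s,
                                      age_bin_edges = age_bin_edges)))
  }
  for (s in subsets) {
    cfgs <- c(cfgs, list(graph_config(use_rsfc = TRUE, phenotype_features = s,
                                      sigma = sigma,
                                      age_bin_edges = age_bin_edges)))
  }
  if (include_baselines) {
    cfgs <- c(cfgs,
              list(graph_config(baseline_kind = "fc"),
                   graph_config(baseline_kind = "identity"),
                   graph_config(baseline_kind = "random",
                                random_density = random_density, seed = seed)))
  }
  names(cfgs) <- vapply(cfgs, `[[`, "", "name")
  cfgs
}

#' Write / read a population graph
#'
#' Dense weights as `<prefix>_weights.csv` (subject ids as header) plus a
#' JSON sidecar `<prefix>_config.json` serializing the configuration.
#'
#' @param graph A `population_graph`.
#' @param prefix File path prefix.
#' @return `prefix`, invisibly.
#' @export
write_population_graph <- function(graph, prefix) {
  stopifnot(inherits(graph, "population_graph"))
  utils::write.csv(as.data.frame(graph$weights),
                   paste0(prefix, "_weights.csv"), row.names = FALSE)
  cfg <- graph$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(subject_ids = graph$subject_ids)),
                       paste0(prefix, "_config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(prefix)
}

#' @rdname write_population_graph
#' @export
read_population_graph <- function(prefix) {
  w <- as.matrix(utils::read.csv(paste0(prefix, "_weights.csv"),
                                 check.names = FALSE))
  cfg <- jsonlite::read_json(paste0(prefix, "_config.json"),
                             simplifyVector = TRUE)
  ids <- cfg$subject_ids
  cfg$subject_ids <- NULL
  if (!is.null(cfg$baseline_kind)) class(cfg) <- "graph_config"
  dimnames(w) <- list(ids, ids)
  new_population_graph(w, cfg, ids)
}

#' Export a graph as an edge-list TSV
#'
#' One row per unordered pair with nonzero weight: columns `subject_i`,
#' `subject_j`, `weight`.
#'
#' @param graph A `population_graph`.
#' @param path Output file.
#' @return The edge-list data frame, invisibly.
#' @export
export_edge_list <- function(graph, path) {
  w <- graph$weights
  up <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  el <- data.frame(subject_i = graph$subject_ids[up[, 1]],
                   subject_j = graph$subject_ids[up[, 2]],
                   weight = w[up])
  utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(el)
}
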