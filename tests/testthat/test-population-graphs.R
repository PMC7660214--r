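# Edge-weight functions, graph construction, baselines, enumeration, I/O.

test_that("the similarity kernel matches its closed form", {
  xi <- c(0.1, 0.5, -0.2, 0.8)
  # identical non-constant vectors: rho = 0 -> similarity 1
  expect_equal(rsfc_similarity(xi, xi, sigma = 0.7), 1)
  # perfect anticorrelation: rho = 2 -> exp(-2) at sigma = 1
  xj <- -xi + 0.3
  expect_equal(pearson_oracle(xi, xj), -1, tolerance = 1e-12)
  expect_equal(rsfc_similarity(xi, xj, sigma = 1), exp(-2), tolerance = 1e-12)
  # constant vector: similarity 0 by convention, no error
  expect_equal(rsfc_similarity(rep(0.4, 4), xi, sigma = 1), 0)
  # symmetry in the arguments
  xk <- c(0.3, -0.1, 0.9, 0.2)
  expect_equal(rsfc_similarity(xi, xk, 0.5), rsfc_similarity(xk, xi, 0.5))
})

test_that("phenotype match counts sum equality indicators", {
  vi <- list(site = 2, sex = "M", age = 7)
  vj <- list(site = 2, sex = "M", age = 9)
  edges <- seq(5, 60, by = 5)
  expect_equal(phenotype_match_count(vi, vj, c("site", "sex")), 2L)
  expect_equal(
    phenotype_match_count(list(site = 1, sex = "F", age = 33), vj,
                          c("site", "sex", "age"), edges), 0L)
  # ages 7 and 9 share the [5, 10) bin
  expect_equal(phenotype_match_count(vi, vj, "age", edges), 1L)
  # missing values match nothing
  expect_equal(phenotype_match_count(list(site = NA), list(site = NA), "site"), 0L)
})

test_that("the RSFC graph equals a brute-force pairwise kernel computation", {
  co <- smooth_cohort(n_per_class = 2, r = 6, seed = 21)
  x <- vectorize_rsfc(co)
  sigma <- 0.8
  g <- build_population_graph(x, co, graph_config(use_rsfc = TRUE, sigma = sigma))
  n <- nrow(x)
  expected <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) expected[i, j] <- rsfc_similarity(x[i, ], x[j, ], sigma)
    }
  }
  expect_equal(unname(g$weights), expected, tolerance = 1e-12)
  expect_equal(g$weights, t(g$weights))
})

test_that("combined graphs factor into kernel times match count", {
  co <- smooth_cohort(n_per_class = 10, r = 8, seed = 31, n_sites = 3)
  x <- vectorize_rsfc(co)
  sigma <- 1
  bins <- c(0, 20, 40, 60)
  rsfc_w <- build_population_graph(x, co, graph_config(use_rsfc = TRUE,
                                                       sigma = sigma))$weights
  subsets <- list("site", "sex", "age", c("site", "sex"),
                  c("site", "age"), c("sex", "age"), c("site", "sex", "age"))
  for (s in subsets) {
    ph <- build_population_graph(x, co,
            graph_config(phenotype_features = s, age_bin_edges = bins))$weights
    comb <- build_population_graph(x, co,
              graph_config(use_rsfc = TRUE, phenotype_features = s,
                           sigma = sigma, age_bin_edges = bins))$weights
    expect_lt(max(abs(comb - rsfc_w * ph)), 1e-12)
    # phenotype-only weights are integers in [0, H]
    expect_true(all(ph == round(ph)))
    expect_true(all(ph >= 0 & ph <= length(s)))
  }
})

test_that("subjects from different sites get zero weight in a site-gated graph", {
  co <- smooth_cohort(n_per_class = 8, r = 6, seed = 41, n_sites = 3)
  x <- vectorize_rsfc(co)
  g <- build_population_graph(x, co,
         graph_config(use_rsfc = TRUE, phenotype_features = "site", sigma = 1))
  site <- co$phenotypes$site
  diff_site <- outer(site, site, "!=")
  expect_true(all(g$weights[diff_site] == 0))
})

test_that("adding phenotype features never decreases match-count weights", {
  co <- smooth_cohort(n_per_class = 8, r = 6, seed = 43, n_sites = 3)
  x <- vectorize_rsfc(co)
  bins <- c(0, 30, 60)
  w1 <- build_population_graph(x, co, graph_config(phenotype_features = "site"))$weights
  w2 <- build_population_graph(x, co,
          graph_config(phenotype_features = c("site", "sex")))$weights
  w3 <- build_population_graph(x, co,
          graph_config(phenotype_features = c("site", "sex", "age"),
                       age_bin_edges = bins))$weights
  expect_true(all(w2 >= w1))
  expect_true(all(w3 >= w2))
})

test_that("permuting subjects permutes the weight matrix consistently", {
  co <- smooth_cohort(n_per_class = 6, r = 6, seed = 47, n_sites = 2)
  x <- vectorize_rsfc(co)
  cfg <- graph_config(use_rsfc = TRUE, phenotype_features = "sex", sigma = 1)
  w <- build_population_graph(x, co, cfg)$weights

  set.seed(7)
  perm <- sample(length(co$subject_ids))
  co_p <- co
  co_p$subject_ids <- co$subject_ids[perm]
  co_p$rsfc <- co$rsfc[perm]
  co_p$phenotypes <- co$phenotypes[perm, ]
  co_p$labels <- co$labels[perm]
  w_p <- build_population_graph(x[perm, , drop = FALSE], co_p, cfg)$weights
  expect_equal(unname(w_p), unname(w[perm, perm]), tolerance = 1e-12)
})

test_that("baseline graphs match their definitions", {
  fc <- build_baseline_graph("fc", 4)
  expect_equal(sum(fc$weights[upper.tri(fc$weights)]), 6)
  expect_true(all(fc$weights[upper.tri(fc$weights)] == 1))

  idg <- build_baseline_graph("identity", 5)
  expect_true(all(idg$weights == 0))
  expect_true(all(combinatorial_laplacian(idg) == 0))

  r1 <- build_baseline_graph("random", 6, density = 1, seed = 2)
  fc6 <- build_baseline_graph("fc", 6)
  expect_equal(r1$weights, fc6$weights)

  rg <- build_baseline_graph("random", 100, density = 0.1, seed = 5)
  n_edges <- sum(rg$weights[upper.tri(rg$weights)])
  bounds <- qbinom(c(0.005, 0.995), choose(100, 2), 0.1)
  expect_gte(n_edges, bounds[1])
  expect_lte(n_edges, bounds[2])

  expect_error(build_baseline_graph("nope", 4), "unknown baseline")
})

test_that("config validation rejects contradictory and empty definitions", {
  expect_error(graph_config(), "empty graph definition")
  expect_error(graph_config(use_rsfc = TRUE, baseline_kind = "fc"), "baseline")
  expect_error(graph_config(phenotype_features = "height"), "unknown phenotype")
})

test_that("config enumeration yields the documented families", {
  cfgs <- enumerate_graph_configs()
  expect_length(cfgs, 15)
  cfgs_b <- enumerate_graph_configs(include_baselines = TRUE)
  expect_length(cfgs_b, 18)
  pheno_only <- Filter(function(g) !g$use_rsfc && g$baseline_kind == "none", cfgs)
  expect_length(pheno_only, 7)
  rsfc_pheno <- Filter(function(g) g$use_rsfc && length(g$phenotype_features) > 0, cfgs)
  expect_length(rsfc_pheno, 7)
  expect_equal(names(cfgs)[1], "sim_RSFC")
  expect_false(any(duplicated(names(cfgs_b))))
})

test_that("graph CSV/JSON round trip and edge-list export work", {
  co <- smooth_cohort(n_per_class = 4, r = 6, seed = 51)
  x <- vectorize_rsfc(co)
  g <- build_population_graph(x, co,
         graph_config(use_rsfc = TRUE, phenotype_features = "sex", sigma = 1))
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "g")
  write_population_graph(g, prefix)
  back <- read_population_graph(prefix)
  expect_equal(back$weights, g$weights, tolerance = 1e-12)
  expect_equal(back$config$name, g$config$name)

  el <- export_edge_list(g, file.path(dir, "edges.tsv"))
  expect_true(file.exists(file.path(dir, "edges.tsv")))
  expect_equal(nrow(el), sum(g$weights[upper.tri(g$weights)] != 0))
})
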