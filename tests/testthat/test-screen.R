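.cells_df <- function(kd, ...) {
  n <- length(kd)
  data.frame(strain = "s", C_g = rep(3e-7, n), C_r = rep(3e-7, n),
             D_g = rnorm(n, 3, 0.2), D_r = rnorm(n, 3, 0.2),
             cpps_g = rnorm(n, 2700, 200), cpps_r = rnorm(n, 1500, 150),
             C_AB = rep(8e-8, n), K_D_app = kd,
             kd_above_range = !is.finite(kd), ...)
}

test_that("strain aggregation computes single-cell mean and sample SD", {
  set.seed(1)
  one <- .cells_df(5e-7)[1, ]
  s1 <- aggregate_strain(one)
  expect_equal(s1$n, 1)
  row <- s1$stats[s1$stats$quantity == "K_D_app", ]
  expect_equal(row$mean, 5e-7)
  expect_true(is.na(row$sd))  # SD only reported for n >= 2

  three <- .cells_df(c(1e-7, 2e-7, 3e-7))
  s3 <- aggregate_strain(three)
  row <- s3$stats[s3$stats$quantity == "K_D_app", ]
  expect_equal(row$mean, 2e-7)
  expect_equal(row$sd, 1e-7)  # n - 1 denominator
  expect_error(aggregate_strain(three[0, ]), "no cell")
})

test_that("aggregation is permutation invariant and censoring-aware", {
  set.seed(2)
  kd <- c(1e-7, Inf, 3e-7, Inf, 2e-7)
  cells <- .cells_df(kd)
  a <- aggregate_strain(cells)
  b <- aggregate_strain(cells[sample(nrow(cells)), ])
  expect_equal(a$stats, b$stats)
  expect_equal(a$kd_median, b$kd_median)
  # sentinels excluded from the mean, counted separately
  row <- a$stats[a$stats$quantity == "K_D_app", ]
  expect_equal(row$mean, 2e-7)
  expect_equal(row$n, 3)
  expect_equal(a$n_sentinel, 2)
})

test_that("interaction classification follows the 1 uM detection bound", {
  set.seed(3)
  # strong self-interaction (127 nM) -> detected
  expect_true(classify_interaction(aggregate_strain(
    .cells_df(rep(1.27e-7, 12)))))
  # all cells above range -> not detected
  expect_false(classify_interaction(aggregate_strain(
    .cells_df(rep(Inf, 12)))))
  # 2 uM -> outside the dynamic range
  expect_false(classify_interaction(aggregate_strain(
    .cells_df(rep(2e-6, 12)))))
  # majority-sentinel strains are not called even if the median sneaks in
  mixed <- .cells_df(c(rep(9e-7, 5), rep(Inf, 7)))
  expect_false(classify_interaction(aggregate_strain(mixed)))
})

test_that("Welch comparison matches stats::t.test and stars correctly", {
  set.seed(4)
  x <- rnorm(12, 2700, 300)
  y <- rnorm(14, 2500, 400)
  sa <- aggregate_strain(.cells_df(rep(5e-7, 12), cpps_override = NA))
  sa$stats[sa$stats$quantity == "cpps_g", c("mean", "sd", "n")] <-
    list(mean(x), sd(x), length(x))
  sb <- aggregate_strain(.cells_df(rep(5e-7, 14)))
  sb$stats[sb$stats$quantity == "cpps_g", c("mean", "sd", "n")] <-
    list(mean(y), sd(y), length(y))
  cmp <- compare_strains(sa, sb, "cpps_g")
  ref <- t.test(x, y)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(cmp$t, unname(ref$statistic), tolerance = 1e-10)
  # symmetry
  cmp2 <- compare_strains(sb, sa, "cpps_g")
  expect_equal(cmp2$p_value, cmp$p_value)
  # identical samples: p = 1, not significant
  same <- compare_strains(sa, sa, "cpps_g")
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")
})

test_that("a 2-fold cpps difference at n = 12 is highly significant", {
  set.seed(5)
  mono <- rnorm(12, 2700, 0.15 * 2700)
  dimer <- rnorm(12, 5400, 0.15 * 5400)
  sa <- aggregate_strain(.cells_df(rep(5e-7, 12)))
  sa$stats[sa$stats$quantity == "cpps_g", c("mean", "sd", "n")] <-
    list(mean(mono), sd(mono), 12L)
  sb <- aggregate_strain(.cells_df(rep(5e-7, 12)))
  sb$stats[sb$stats$quantity == "cpps_g", c("mean", "sd", "n")] <-
    list(mean(dimer), sd(dimer), 12L)
  cmp <- compare_strains(sa, sb, "cpps_g")
  expect_lte(cmp$p_value, 0.001)
  expect_equal(cmp$stars, "***")
})

test_that("network export round-trips through GraphML", {
  set.seed(6)
  summaries <- list(
    Ede1 = aggregate_strain(.cells_df(rep(1.27e-7, 12)), strain = "Ede1"),
    Syp1 = aggregate_strain(.cells_df(rep(2.27e-7, 12)), strain = "Syp1"),
    Ent1 = aggregate_strain(.cells_df(rep(Inf, 12)), strain = "Ent1"))
  records <- list(
    interaction_record("Ede1", "Ede1",
                       aggregate_strain(.cells_df(rep(1.27e-7, 12)))),
    interaction_record("Ede1", "Syp1",
                       aggregate_strain(.cells_df(rep(2.27e-7, 12)))),
    interaction_record("Ede1", "Ent1",
                       aggregate_strain(.cells_df(rep(Inf, 12)))))
  path <- file.path(tempdir(), "net.graphml")
  g <- export_network(records, summaries, path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(tempdir(), "net_edges.tsv")))
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(sort(igraph::V(back)$name), c("Ede1", "Ent1", "Syp1"))
  expect_equal(igraph::ecount(back), 3)
  expect_equal(sum(igraph::E(back)$detected), 2)
  # self-interaction present as a loop
  expect_true(any(igraph::which_loop(back)))
  # strongest detected edge has weight 1; undetected edges weight 0
  expect_equal(max(igraph::E(back)$weight), 1)
  expect_equal(min(igraph::E(back)$weight), 0)
})

test_that("network export validates node labels and handles empty input", {
  set.seed(7)
  summaries <- list(A = aggregate_strain(.cells_df(rep(1e-7, 3)),
                                         strain = "A"))
  rec <- list(interaction_record("A", "Zzz",
                                 aggregate_strain(.cells_df(rep(1e-7, 3)))))
  expect_error(export_network(rec, summaries,
                              file.path(tempdir(), "x.graphml")), "Zzz")
  path <- file.path(tempdir(), "empty.graphml")
  g <- export_network(list(), summaries, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 1)
  expect_equal(igraph::ecount(back), 0)
})
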