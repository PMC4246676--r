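mk_metab <- function(compound, accession, values) {
  data.frame(compound = compound, accession = accession,
             bio_rep = seq_along(values), tech_rep = 1L, value = values,
             stringsAsFactors = FALSE)
}

test_that("pooling sums member means over biological replicates", {
  metab <- rbind(mk_metab("c1", "A", c(1, 2, 3)),
                 mk_metab("c2", "A", c(10, 20, 30)),
                 mk_metab("c1", "B", c(1, 1, 1)),
                 mk_metab("c2", "B", c(2, 2, 2)))
  pools <- data.frame(pool_id = "P1", compound = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  pooled <- pool_levels(metab, pools)
  a <- pooled[pooled$accession == "A", ]
  expect_equal(a$value[order(a$bio_rep)], c(11, 22, 33))
  expect_true(all(pooled$complete))
})

test_that("technical replicates are averaged before pooling", {
  metab <- data.frame(compound = "c1", accession = "A",
                      bio_rep = c(1L, 1L, 2L, 2L),
                      tech_rep = c(1L, 2L, 1L, 2L),
                      value = c(10, 20, 30, 50), stringsAsFactors = FALSE)
  metab <- rbind(metab, within(metab, accession <- "B"))
  pools <- data.frame(pool_id = "P1", compound = "c1",
                      stringsAsFactors = FALSE)
  pooled <- pool_levels(metab, pools)
  a <- pooled[pooled$accession == "A", ]
  expect_equal(a$value[order(a$bio_rep)], c(15, 40))
})

test_that("a single-compound pool equals that compound's replicate means", {
  metab <- rbind(mk_metab("c1", "A", c(4, 5, 6)), mk_metab("c1", "B", c(7, 8, 9)))
  pools <- data.frame(pool_id = "P1", compound = "c1",
                      stringsAsFactors = FALSE)
  pooled <- pool_levels(metab, pools)
  expect_equal(sort(pooled$value), c(4, 5, 6, 7, 8, 9))
})

test_that("a member missing in one accession flags the pool incomplete", {
  metab <- rbind(mk_metab("c1", "A", c(1, 2)), mk_metab("c2", "A", c(1, 2)),
                 mk_metab("c1", "B", c(1, 2)))
  pools <- data.frame(pool_id = "P1", compound = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  pooled <- pool_levels(metab, pools)
  expect_true(all(!pooled$complete))
  # incomplete pools are skipped by the comparison stage
  expect_null(compare_pools(pooled, "A", "B"))
})

test_that("pool comparison: identical samples give p = 1", {
  pooled <- data.frame(pool_id = "P1", accession = rep(c("A", "B"), each = 3),
                       bio_rep = rep(1:3, 2), value = rep(5, 6),
                       complete = TRUE, stringsAsFactors = FALSE)
  res <- compare_pools(pooled, "A", "B")
  expect_equal(res$pvalue, 1)
  expect_false(res$significant)
  expect_identical(res$direction, "none")
})

test_that("pool comparison: clearly separated samples are significant", {
  pooled <- data.frame(pool_id = "P1", accession = rep(c("A", "B"), each = 3),
                       bio_rep = rep(1:3, 2),
                       value = c(10, 11, 12, 20, 21, 22),
                       complete = TRUE, stringsAsFactors = FALSE)
  res <- compare_pools(pooled, "A", "B")
  expect_lt(res$pvalue, 0.01)
  expect_identical(res$direction, "B")
  # against the established Welch implementation directly
  expect_equal(res$pvalue,
               stats::t.test(c(10, 11, 12), c(20, 21, 22))$p.value)
})

test_that("pool comparison refuses n = 1 per side", {
  pooled <- data.frame(pool_id = "P1", accession = c("A", "B", "B"),
                       bio_rep = c(1, 1, 2), value = c(1, 2, 3),
                       complete = TRUE, stringsAsFactors = FALSE)
  expect_error(compare_pools(pooled, "A", "B"), ">= 2 biological replicates")
})

test_that("pooling is linear: scaling members scales the pool, same p", {
  metab <- rbind(mk_metab("c1", "A", c(1, 2, 3)),
                 mk_metab("c2", "A", c(4, 5, 6)),
                 mk_metab("c1", "B", c(2, 3, 4)),
                 mk_metab("c2", "B", c(8, 9, 10)))
  pools <- data.frame(pool_id = "P1", compound = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  p1 <- pool_levels(metab, pools)
  metab2 <- metab; metab2$value <- metab2$value * 7
  p2 <- pool_levels(metab2, pools)
  expect_equal(p2$value, 7 * p1$value)
  expect_equal(compare_pools(p2, "A", "B")$pvalue,
               compare_pools(p1, "A", "B")$pvalue, tolerance = 1e-12)
})

test_that("null simulations reject at about the nominal 5% rate", {
  cfg <- scenario_config(seed = 17)
  n_pools <- 1000
  pools <- data.frame(pool_id = sprintf("P%04d", seq_len(n_pools)),
                      compound = sprintf("c%04d", seq_len(n_pools)),
                      stringsAsFactors = FALSE)
  metab <- simulate_metabolites(pools, cfg)
  tests <- compare_pools(pool_levels(metab, pools), "A", "B")
  rate <- mean(tests$significant)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted 4-fold shifts at CV 10%, n = 3 are almost always detected", {
  n_pools <- 500
  pools <- data.frame(pool_id = sprintf("P%04d", seq_len(n_pools)),
                      compound = sprintf("c%04d", seq_len(n_pools)),
                      stringsAsFactors = FALSE)
  cfg <- scenario_config(seed = 18)
  metab <- simulate_metabolites(pools, cfg, shifted_pools = pools$pool_id,
                                fold = 4)
  tests <- compare_pools(pool_levels(metab, pools), "A", "B")
  expect_gte(mean(tests$significant & tests$direction == "A"), 0.95)
})

test_that("crosstab: trivial all/none fractions and the half-shifted scenario", {
  resp <- data.frame(reaction_id = c("R1", "R2"),
                     combined_call = c("T", "S"), stringsAsFactors = FALSE)
  links <- data.frame(pool_id = c("P1", "P2"), reaction_id = c("R1", "R2"),
                      stringsAsFactors = FALSE)
  tests <- data.frame(pool_id = c("P1", "P2"), mean_A = 1, mean_B = 2,
                      pvalue = c(0.01, 0.02), significant = TRUE,
                      direction = "B", stringsAsFactors = FALSE)
  expect_equal(crosstab_flux_metabolite(tests, resp, links)$fraction_shifted, 1)
  tests$significant <- FALSE; tests$direction <- "none"
  expect_equal(crosstab_flux_metabolite(tests, resp, links)$fraction_shifted, 0)

  # synthetic scenario: 40 pools linked to flux-changed reactions, half shifted
  n <- 40
  pools <- data.frame(pool_id = sprintf("P%03d", 1:n),
                      compound = sprintf("c%03d", 1:n),
                      stringsAsFactors = FALSE)
  links <- data.frame(pool_id = pools$pool_id,
                      reaction_id = sprintf("R%03d", 1:n),
                      stringsAsFactors = FALSE)
  resp <- data.frame(reaction_id = links$reaction_id,
                     combined_call = rep(c("T", "S"), n / 2),
                     stringsAsFactors = FALSE)
  cfg <- scenario_config(seed = 19)
  metab <- simulate_metabolites(pools, cfg,
                                shifted_pools = pools$pool_id[1:(n / 2)],
                                fold = 4)
  tests <- compare_pools(pool_levels(metab, pools), "A", "B")
  ct <- crosstab_flux_metabolite(tests, resp, links)
  expect_gte(ct$fraction_shifted, 0.35)
  expect_lte(ct$fraction_shifted, 0.65)
  expect_equal(nrow(ct$table), n)
})

test_that("metabolite tables round-trip through TSV", {
  pools <- data.frame(pool_id = "P1", compound = c("c1", "c2"),
                      stringsAsFactors = FALSE)
  metab <- simulate_metabolites(pools, scenario_config(seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_metabolites(metab, path)
  back <- read_metabolites(path)
  expect_equal(back$value, metab$value)
  expect_identical(back$compound, metab$compound)
  expect_identical(back$accession, metab$accession)
})
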