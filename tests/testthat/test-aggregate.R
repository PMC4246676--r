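test_that("combine_calls implements the stringent rule", {
  expect_equal(combine_calls(c("T", "T", "N")), "T")
  expect_equal(combine_calls(c("T", "S")), "N")
  expect_equal(combine_calls(c("N", "N", "X")), "N")
  expect_equal(combine_calls(c("S", "S", "X", "N")), "S")
  expect_error(combine_calls(character(0)), "empty")
  expect_error(combine_calls(c("T", "Q")), "unknown")
})

test_that("combine_calls properties hold over all multisets of size <= 5", {
  syms <- c("T", "S", "N", "X")
  for (size in 1:5) {
    combos <- do.call(expand.grid,
                      c(rep(list(syms), size), stringsAsFactors = FALSE))
    for (i in seq_len(nrow(combos))) {
      calls <- as.character(combos[i, ])
      res <- combine_calls(calls)
      # order invariance
      expect_identical(res, combine_calls(rev(calls)))
      expect_identical(res, combine_calls(sort(calls)))
      # any mixture of T and S collapses to N
      if (all(c("T", "S") %in% calls)) expect_identical(res, "N")
      # idempotence through a second application
      expect_identical(combine_calls(res), if (res == "N") "N" else res)
    }
  }
  # singletons
  expect_identical(combine_calls("T"), "T")
  expect_identical(combine_calls("S"), "S")
  expect_identical(combine_calls("N"), "N")
  expect_identical(combine_calls("X"), "N")
})

test_that("call strings from the matched-reaction table parse correctly", {
  expect_identical(parse_call_string("(S)()()()()"),
                   list("S", character(0), character(0), character(0),
                        character(0)))
  groups <- parse_call_string("()()(S)(SSS)(SS)()()()()")
  expect_length(groups, 9)
  expect_identical(lengths(groups), c(0L, 0L, 1L, 3L, 2L, 0L, 0L, 0L, 0L))
  expect_identical(parse_call_string("(TTTT)"), list(c("T", "T", "T", "T")))
  expect_identical(parse_call_string("(TT)()(X)(T)"),
                   list(c("T", "T"), character(0), "X", "T"))
})

test_that("invalid call strings are rejected with a position", {
  expect_error(parse_call_string("(T"), "unbalanced")
  expect_error(parse_call_string("(T))"), "position 4")
  expect_error(parse_call_string("((T))"), "nested.*position 2")
  expect_error(parse_call_string("(TQ)"), "'Q' at position 3")
  expect_error(parse_call_string("T(T)"), "outside parentheses at position 1")
  expect_error(parse_call_string("(TX)"), "stand alone")
})

test_that("call strings aggregate to the expected reaction calls", {
  expect_equal(call_string_reaction_call("()()(X)()()(TT)"), "T")
  expect_equal(call_string_reaction_call("()(TT)"), "T")
  expect_equal(call_string_reaction_call("(S)(S)()"), "S")
  expect_equal(call_string_reaction_call("(T)(S)"), "N")
  expect_equal(call_string_reaction_call("(TS)()"), "N")
  expect_equal(call_string_reaction_call("(X)(X)"), "X")
  expect_equal(call_string_reaction_call("()()"), "N")
})

test_that("every matched-reaction fixture row round-trips (27/27)", {
  ref <- reference_matched_reactions()
  expect_equal(nrow(ref), 27L)
  derived <- vapply(ref$call_string, call_string_reaction_call, "",
                    USE.NAMES = FALSE)
  expect_identical(derived, ref$expression_call)
  # every row is direction-matched: expression call equals flux call
  expect_identical(ref$expression_call, ref$flux_call)
})

test_that("gene aggregation computes calls, sums and agreement", {
  tcalls <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5"),
    call = c("T", "T", "T", "S", "N"),
    mean_A = c(300, 200, 50, 10, 5),
    mean_B = c(60, 40, 40, 100, 5),
    stringsAsFactors = FALSE)
  gpr <- list(
    transcript_map = data.frame(
      transcript_id = c("t1", "t2", "t3", "t4", "t5"),
      gene_id = c("g1", "g1", "g2", "g2", "g3"),
      stringsAsFactors = FALSE),
    reaction_map = data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                              reaction_id = c("R1", "R1", "R2", "R3"),
                              stringsAsFactors = FALSE))
  g <- aggregate_to_genes(tcalls, gpr)
  g <- g[order(g$gene_id), ]
  expect_identical(g$gene_id, c("g1", "g2", "g3"))
  expect_identical(g$call, c("T", "N", "N"))   # g2 has a T/S conflict
  expect_equal(g$sum_A, c(500, 60, 5))
  expect_equal(g$sum_B, c(100, 140, 5))
  expect_identical(g$agreement, c(TRUE, NA, NA))

  r <- aggregate_to_reactions(g, gpr)
  r <- r[order(r$reaction_id), ]
  expect_identical(r$reaction_id, c("R1", "R2", "R3"))
  # R1: genes T + N -> T; R2: N; R3: gene absent from expression data -> X
  expect_identical(r$call, c("T", "N", "X"))
})

test_that("a tie in summed expression counts as disagreement", {
  tcalls <- data.frame(transcript_id = "t1", call = "T",
                       mean_A = 100, mean_B = 100, stringsAsFactors = FALSE)
  gpr <- list(transcript_map = data.frame(transcript_id = "t1", gene_id = "g1",
                                          stringsAsFactors = FALSE),
              reaction_map = data.frame(gene_id = "g1", reaction_id = "R1",
                                        stringsAsFactors = FALSE))
  expect_false(aggregate_to_genes(tcalls, gpr)$agreement)
})

test_that("unmapped transcripts are excluded with a warning", {
  tcalls <- data.frame(transcript_id = c("t1", "zz"), call = c("T", "S"),
                       mean_A = c(10, 10), mean_B = c(1, 100),
                       stringsAsFactors = FALSE)
  gpr <- list(transcript_map = data.frame(transcript_id = "t1", gene_id = "g1",
                                          stringsAsFactors = FALSE),
              reaction_map = data.frame(gene_id = "g1", reaction_id = "R1",
                                        stringsAsFactors = FALSE))
  expect_warning(g <- aggregate_to_genes(tcalls, gpr), "without gene mapping")
  expect_equal(nrow(g), 1L)
  expect_identical(g$gene_id, "g1")
})

test_that("category tabulation reproduces the printed ratio convention", {
  expect_equal(bin_ratio(29, 9), 3.22)
  expect_equal(bin_ratio(15, 1), 15)
  expect_equal(bin_ratio(2, 0), Inf)
  gene_calls <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    call = c("T", "T", "S", "N", "T", "S"),
    stringsAsFactors = FALSE)
  categories <- data.frame(
    gene_id = sprintf("g%d", 1:5),
    bin_code = c("1", "1", "1", "1", "32"),
    bin_name = c(rep("photosynthesis", 4), "micro RNA"),
    stringsAsFactors = FALSE)
  tab <- tabulate_categories(gene_calls, categories)
  b1 <- tab[tab$bin_code == "1", ]
  expect_equal(b1$n_T, 2L)
  expect_equal(b1$n_S, 1L)
  expect_equal(b1$ratio, 2)
  b32 <- tab[tab$bin_code == "32", ]
  expect_equal(b32$n_S, 0L)
  expect_equal(b32$ratio, Inf)
  # uncategorized significant gene lands in "not assigned"
  expect_true("not assigned" %in% tab$bin_name)
  # N-only categories are omitted: g4 is BIN 1 but N, already counted category
  expect_false(any(tab$n_S + tab$n_T == 0))
})

test_that("aggregating conflict-free planted truth recovers gene truth", {
  cfg <- scenario_config(seed = 5, n_reactions = 60)
  sim <- simulate_flux_bounds(cfg)
  gpr <- make_gpr(cfg, sim$truth$reaction_id)
  truth <- plant_concordance(sim$truth, beta = 1, gpr, cfg)
  counts <- simulate_counts(gpr, truth, cfg)
  calls <- call_transcripts(de_test(counts$counts))
  g <- aggregate_to_genes(calls, gpr)
  # restrict to genes whose transcripts were all called the planted direction
  planted <- stats::setNames(truth$direction, truth$gene_id)
  tx_gene <- gpr$transcript_map$gene_id[
    match(calls$transcript_id, gpr$transcript_map$transcript_id)]
  all_correct <- tapply(calls$call == planted[tx_gene], tx_gene, all)
  eligible <- names(all_correct)[all_correct]
  hit <- g$call[match(eligible, g$gene_id)] == planted[eligible]
  expect_gte(mean(hit), 0.99)
})
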