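test_that("weight-matrix training gives pseudocounted column frequencies", {
  p <- 0.5
  m <- train_splice_model(rep("CAGGTAAGT", 10), "donor", "wmm",
                          pseudocount = p)
  # closed form at the invariant +1 position (all 10 training bases G)
  expect_equal(unname(m$prob["G", 4]), (10 + p) / (10 + 4 * p))
  expect_equal(unname(m$prob["A", 4]), p / (10 + 4 * p))
  # probability columns sum to 1
  expect_true(all(abs(colSums(m$prob) - 1) < 1e-9))
})

test_that("weight-array training reproduces deterministic conditionals", {
  # every training sequence pairs G at +1 with T at +2: P(T|G) ~ 1
  seqs <- toy_donor_training()
  m <- train_splice_model(seqs, "donor", "wam", pseudocount = 0.1)
  expect_true(all(abs(vapply(m$cond, rowSums, numeric(4)) - 1) < 1e-9))
  p <- m$cond[[4]]["G", "T"]   # transition +1 -> +2
  n <- length(seqs)
  expect_equal(p, (n + 0.1) / (n + 0.4))

  expect_error(train_splice_model(c("CAGGTAAGT", "CAG"), "donor", "wmm"),
               "ragged")
  expect_error(train_splice_model("CAGGTAAGT", "donor", "wmm"),
               "at least 2")
})

test_that("scores are min-max normalized over the attainable range", {
  m <- train_splice_model(rep("CAGGTAAGT", 10), "donor", "wmm")
  # the training consensus attains the model maximum
  expect_equal(score_site(m, "CAGGTAAGT"), 1.0)

  # a raw log-odds of zero maps to the midpoint prescribed by the range
  expected_zero <- (0 - m$range[1]) / (m$range[2] - m$range[1])
  expect_equal(score_site(m, strrep("N", 9)), expected_zero)

  # GT -> AT destroys the site: score drops below the recognition
  # threshold for models trained on canonical donors
  mut <- "CAGATAAGT"
  expect_lt(score_site(m, mut), predictor_params()$recognition_threshold)
  # hand-computed: the mutant loses exactly the +1 column's range
  cols <- log(m$prob / 0.25)
  drop <- max(cols[, 4]) - unname(cols["A", 4])
  expect_equal(score_site(m, mut),
               1 - drop / (m$range[2] - m$range[1]))

  expect_error(score_site(m, "CAG"), "length")
})

test_that("wild-type/mutant prediction follows the three-way consensus", {
  methods <- c("wmm", "wam", "consensus_ic")
  models <- stats::setNames(lapply(methods, function(me) {
    train_splice_model(toy_donor_training(), "donor", me)
  }), methods)

  expect_error(predict_splice_loss("CAGGTAAGT", "CAGGTAAGT", models),
               "no-variant")

  # canonical donor, +1 G>A: unanimous loss
  pred <- predict_splice_loss("CAGGTAAGT", "CAGATAAGT", models)
  expect_equal(pred$effect, "donor_lost")
  expect_true(pred$consensus)
  expect_gt(pred$probability, 0)
  expect_lte(pred$probability, 1)
  for (m in pred$methods) {
    expect_true(m$wt_recognized)
    expect_false(m$mut_recognized)
  }

  # a variant at a weakly constrained position leaves the site recognized
  pred <- predict_splice_loss("CAGGTAAGT", "TAGGTAAGT", models)
  expect_equal(pred$effect, "none")
  expect_false(pred$consensus)
})

test_that("GT/AG-destroying mutations always score below wild type", {
  models <- default_splice_models()
  don_wt <- "CAGGTAAGT"
  acc_wt <- paste0(strrep("C", 18), "AGGAG")
  cases <- list(
    list(models$donor, don_wt, 4, c("A", "C", "T")),   # +1
    list(models$donor, don_wt, 5, c("A", "C", "G")),   # +2
    list(models$acceptor, acc_wt, 19, c("C", "G", "T")), # -2
    list(models$acceptor, acc_wt, 20, c("A", "C", "T"))) # -1
  for (cs in cases) {
    for (b in cs[[4]]) {
      mut <- cs[[2]]
      substr(mut, cs[[3]], cs[[3]]) <- b
      for (m in cs[[1]]) {
        expect_lt(score_site(m, mut), score_site(m, cs[[2]]))
      }
    }
  }
})

test_that("prediction is deterministic and monotone in the method set", {
  models <- default_splice_models()$donor
  p1 <- predict_splice_loss("CAGGTAAGT", "CAGATAAGT", models)
  p2 <- predict_splice_loss("CAGGTAAGT", "CAGATAAGT", models)
  expect_identical(p1, p2)
  # removing a method can only keep or add losses
  for (drop in names(models)) {
    sub <- predict_splice_loss("CAGGTAAGT", "CAGATAAGT",
                               models[setdiff(names(models), drop)])
    expect_true(sub$consensus >= p1$consensus)
  }
})

test_that("batch prediction scores each side with its own models", {
  sc <- build_scenario("gnaq_skip", withr::local_tempdir())
  genome <- load_fasta(sc$paths$genome)
  txs <- load_gene_models(sc$paths$gtf)
  variants <- cross_match(parse_pileup(sc$paths$tumor),
                          parse_pileup(sc$paths$normal))
  ann <- classify_variants(variants, txs)
  pred <- batch_predict(ann, genome, txs)
  expect_equal(nrow(pred), 1L)
  expect_equal(pred$effect, "donor_lost")
  expect_true(pred$consensus)

  # a planted acceptor -1 G>A yields acceptor_lost, matching the side
  sc2 <- build_scenario("hook1_retention", withr::local_tempdir())
  g2 <- load_fasta(sc2$paths$genome)
  t2 <- load_gene_models(sc2$paths$gtf)
  v2 <- cross_match(parse_pileup(sc2$paths$tumor),
                    parse_pileup(sc2$paths$normal))
  a2 <- classify_variants(v2, t2)
  p2 <- batch_predict(a2, g2, t2)
  expect_equal(p2$effect, "acceptor_lost")
  expect_equal(p2$side, "acceptor")
})

test_that("all-wild-type fixtures yield zero losses", {
  sc <- build_scenario("negative_control", withr::local_tempdir())
  genome <- load_fasta(sc$paths$genome)
  txs <- load_gene_models(sc$paths$gtf)
  variants <- cross_match(parse_pileup(sc$paths$tumor),
                          parse_pileup(sc$paths$normal))
  ann <- classify_variants(variants, txs)
  pred <- batch_predict(ann, genome, txs)
  expect_equal(nrow(pred), 0L)
})

test_that("deep splice-region variants outside the scored window are
           reported unevaluated", {
  sc <- build_scenario("apc_homozygous", withr::local_tempdir())
  genome <- load_fasta(sc$paths$genome)
  txs <- load_gene_models(sc$paths$gtf)
  tx <- txs[[1]]
  don <- splice_boundaries(tx)
  don <- don[don$kind == "donor", ][1, ]
  # +15 is within the 20 bp splice window but outside the 9-mer donor model
  v <- data.frame(contig = tx$contig, position = don$genomic_position + 15L,
                  ref_base = substr(genome[[tx$contig]],
                                    don$genomic_position + 15L,
                                    don$genomic_position + 15L),
                  alt_base = "A", tumor_depth = 30L, tumor_alt_count = 10L,
                  tumor_percent = 33L, normal_depth = 30L,
                  normal_alt_count = 0L, normal_percent = 0L,
                  multi_allelic = FALSE, stringsAsFactors = FALSE)
  if (v$ref_base == "A") v$alt_base <- "C"
  ann <- classify_variants(v, txs)
  pred <- batch_predict(ann, genome, txs)
  expect_false(pred$in_window)
  expect_equal(pred$effect, "none")
})

test_that("model serialization round-trips through JSON", {
  models <- default_splice_models()
  f <- withr::local_tempfile(fileext = ".json")
  write_splice_models(models, f)
  back <- read_splice_models(f)
  for (side in c("donor", "acceptor")) {
    for (m in names(models[[side]])) {
      for (w in c("CAGGTAAGT", "CATGTCAGT")[
          if (side == "donor") 1:2 else integer(0)]) {
        expect_equal(score_site(back[[side]][[m]], w),
                     score_site(models[[side]][[m]], w))
      }
    }
  }
  w23 <- paste0(strrep("C", 18), "AGGAG")
  for (m in names(models$acceptor)) {
    expect_equal(score_site(back$acceptor[[m]], w23),
                 score_site(models$acceptor[[m]], w23))
  }
})
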