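test_that("label rank uses competition ranking with deterministic ties", {
  p <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(label_rank(p, "a"), 1L)
  expect_equal(label_rank(p, "c"), 3L)
  u <- setNames(rep(0.25, 4), letters[1:4])
  expect_equal(label_rank(u, "a"), 1L)  # vocabulary-first wins ties
  expect_equal(label_rank(u, "c"), 3L)
  expect_error(label_rank(p, "zebra"), "unknown")
  # full-sort oracle on large random vectors
  set.seed(9)
  vocab <- sprintf("l%04d", 1:1000)
  for (i in 1:20) {
    v <- setNames(runif_probs(1000), vocab)
    lab <- sample(vocab, 1)
    oracle <- match(lab, vocab[order(-v, seq_along(v))])
    expect_equal(label_rank(v, lab), oracle)
  }
})

test_that("top-k membership is consistent with rank and monotone in k", {
  set.seed(10)
  vocab <- sprintf("l%03d", 1:50)
  for (i in 1:50) {
    v <- setNames(runif_probs(50), vocab)
    lab <- sample(vocab, 1)
    r <- label_rank(v, lab)
    for (k in c(1L, 5L, 25L, 50L))
      expect_equal(in_topk(v, lab, k), r <= k)
  }
  v <- setNames(runif_probs(50), vocab)
  expect_true(in_topk(v, vocab[1], 50L))
  expect_error(in_topk(v, vocab[1], 0L), "k")
})

test_that("chance level is exactly 1/K", {
  expect_identical(chance_level(1000), 0.001)  # the 0.1% baseline
  expect_identical(chance_level(1), 1)
  expect_identical(chance_level(4), 0.25)
  expect_error(chance_level(0), "K")
})

test_that("shape/texture preference compares strictly and reports ties", {
  p <- c(teapot = 0.3, golfball = 0.1, other = 0.6)
  expect_equal(shape_texture_preference(p, "teapot", "golfball"), "shape")
  expect_equal(shape_texture_preference(p, "golfball", "teapot"), "texture")
  q <- c(a = 0.2, b = 0.2, c = 0.6)
  expect_equal(shape_texture_preference(q, "a", "b"), "tie")
  expect_error(shape_texture_preference(p, "teapot", "teapot"), "distinct")
})

test_that("a constructed 40-item chimera set reproduces a 17/23 preference split", {
  vocab <- c(sprintf("shape%02d", 1:40), sprintf("tex%02d", 1:40))
  outcomes <- lapply(1:40, function(i) {
    p <- setNames(rep(0.001, 80), vocab)
    winner_is_shape <- i <= 17
    p[i] <- if (winner_is_shape) 0.15 else 0.05
    p[40 + i] <- if (winner_is_shape) 0.05 else 0.15
    p <- p / sum(p)
    classification_outcome(
      stimulus_record(vocab[i], "chimera", texture_label = vocab[40 + i],
                      item_id = paste0("it", i)),
      p)
  })
  tab <- summarize_outcomes(outcomes)
  expect_equal(tab$n_prefer_shape, 17L)
  expect_equal(tab$n_prefer_texture, 23L)
})

test_that("target-vs-group-mean comparison is strict and calibrated under the null", {
  p <- setNames(c(0.5, rep(0.05, 9), 0.05), c("goose", paste0("a", 1:9), "x"))
  res <- vs_class_mean(p, "goose", paste0("a", 1:9))
  expect_true(res$higher)
  expect_equal(res$p_target, 0.5)
  expect_equal(res$mean_others, 0.05)
  u <- setNames(rep(0.1, 10), c("goose", paste0("a", 1:9)))
  expect_false(vs_class_mean(u, "goose", paste0("a", 1:9))$higher)  # strict
  expect_error(vs_class_mean(p, "goose", c("goose", "a1")), "overlap")
  # Monte-Carlo null: 1 target vs the mean of 9 exchangeable others
  set.seed(77)
  hits <- mean(replicate(10000, {
    v <- setNames(runif_probs(10), c("t", paste0("o", 1:9)))
    vs_class_mean(v, "t", paste0("o", 1:9))$higher
  }))
  expect_lt(abs(hits - 0.5), 0.02)
})

test_that("summaries aggregate counts, ranks and the between-group mean ratio", {
  vocab <- sprintf("c%02d", 1:20)
  set.seed(3)
  outcomes <- lapply(1:40, function(i) {
    lab <- vocab[(i - 1) %% 20 + 1]
    p <- setNames(runif_probs(20), vocab)
    if (i <= 5) p[lab] <- max(p) + 0.5  # exactly 5 forced top-1 hits ...
    else if (which.max(p) == match(lab, vocab))  # ... and no accidental ones
      p[c(match(lab, vocab), which.min(p))] <- p[c(which.min(p), match(lab, vocab))]
    p <- p / sum(p)
    classification_outcome(stimulus_record(lab, "silhouette",
                                           item_id = paste0("i", i)), p)
  })
  tab <- summarize_outcomes(outcomes)
  expect_equal(tab$n_top1_correct, 5L)
  expect_equal(tab$n, 40L)
  # mean rank agrees with the per-item oracle
  oracle <- mean(vapply(outcomes, function(o)
    label_rank(setNames(o$probs, o$vocabulary), o$record$shape_label), integer(1)))
  expect_equal(tab$mean_rank, oracle)
  # permutation invariance
  perm <- sample(40)
  tab2 <- summarize_outcomes(outcomes[perm])
  expect_equal(tab$mean_prob_shape, tab2$mean_prob_shape)
  # two groups: ratio of mean shape probabilities, printed means 17.90 / 1.75
  fix_p <- function(o, ps) {
    o$probs <- rep((1 - ps) / 19, 20)
    o$probs[match(o$record$shape_label, o$vocabulary)] <- ps
    o
  }
  g1 <- lapply(outcomes[1:20], fix_p, ps = 0.1790)
  g2 <- lapply(outcomes[21:40], fix_p, ps = 0.0175)
  tabr <- summarize_outcomes(c(g1, g2),
                             factor(rep(c("artifact", "animal"), each = 20),
                                    levels = c("artifact", "animal")))
  expect_false(is.null(attr(tabr, "ratio_of_means")))
  expect_equal(round(attr(tabr, "ratio_of_means")), 10)
})

test_that("human scoring reproduces per-item and per-condition accuracies", {
  # 10 subjects x 6 items; per-item accuracies chosen to match a known table
  props_1s <- c(Camel = 1.0, Hammer = 1.0, Microphone = 0.9, Warplane = 0.9,
                Shirt = 1.0, Violin = 0.7)
  items <- names(props_1s)
  resp <- do.call(rbind, lapply(items, function(it) {
    correct <- rep(c(TRUE, FALSE), c(props_1s[it] * 10, 10 - props_1s[it] * 10))
    data.frame(subject = paste0("s", 1:10), item = it, condition = "serrated",
               display_time = "1s", correct = correct)
  }))
  scored <- score_human(human_responses(resp$subject, resp$item, resp$condition,
                                        resp$display_time, resp$correct))
  expect_equal(sort(scored$per_item$prop_correct), sort(unname(props_1s)))
  expect_equal(scored$per_condition$mean_accuracy, mean(props_1s))
  expect_equal(round(100 * scored$per_condition$mean_accuracy, 2), 91.67)
  # duplicate keys are rejected
  expect_error(human_responses(c("s1", "s1"), c("i", "i"),
                               c("serrated", "serrated"), c("1s", "1s"),
                               c(TRUE, FALSE)), "duplicate")
})

test_that("pooled t test matches the textbook formula and handles degeneracy", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(10, 0.9, 0.05)
    b <- rnorm(10, 0.85, 0.07)
    res <- two_sample_t(a, b)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    p_oracle <- 2 * pt(-abs(t_oracle), 18)
    expect_equal(res$t, t_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_equal(res$df, 18L)  # two groups of 10 pool to 18 df
  }
  same <- rep(0.9, 5)
  res <- two_sample_t(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_error(two_sample_t(rep(1, 5), rep(0, 5)), "variance")
  expect_error(two_sample_t(1, c(1, 2)), "subjects")
})

test_that("probability-vector validation reports deficits without throwing", {
  expect_true(validate_probs(rep(0.25, 4))$ok)
  expect_true(validate_probs(c(1, 0, 0))$ok)
  bad <- validate_probs(c(0.5, 0.4))
  expect_false(bad$ok)
  expect_match(bad$problems, "deficit", all = FALSE)
  expect_false(validate_probs(c(-0.1, 1.1))$ok)
  expect_false(validate_probs(rep(0.25, 4), labels = c("a", "a", "b", "c"))$ok)
})

test_that("outcome tables carry the top-five report layout", {
  vocab <- letters[1:6]
  o <- classification_outcome(
    stimulus_record("c", "chimera", texture_label = "e", item_id = "x1"),
    setNames(c(0.05, 0.1, 0.4, 0.15, 0.2, 0.1), vocab))
  tab <- outcome_table(list(o))
  expect_equal(tab$rank_shape, 1L)
  expect_true(tab$top1_correct)
  expect_equal(strsplit(tab$top5_labels, ";")[[1]][1], "c")
  expect_equal(tab$p_texture, 0.2)
  path <- tempfile(fileext = ".csv")
  outcome_table(list(o), path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("csv$", "json", path)))
})
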