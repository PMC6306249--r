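#' Competition rank of a label in a probability vector
#'
#' Rank 1 + the number of labels with strictly greater probability
#' ("competition" or "1224" ranking); among tied probabilities the
#' vocabulary order decides, which keeps reports deterministic.
#'
#' @param probs named probability vector, or unnamed with `vocabulary`.
#' @param label label whose rank is wanted.
#' @param vocabulary character vector of labels aligned to `probs`
#'   (defaults to `names(probs)`).
#' @return integer rank in `[1, K]`.
#' @export
label_rank <- function(probs, label, vocabulary = names(probs)) {
  if (is.null(vocabulary)) stop("probs must be named or a vocabulary given")
  i <- match(label, vocabulary)
  if (is.na(i)) stop(sprintf("unknown label '%s'", label))
  p <- as.numeric(probs)
  1L + sum(p > p[i]) + sum(p == p[i] & seq_along(p) < i)
}

#' Is a label among the top-k classifications?
#'
#' The top-five criterion of large-vocabulary benchmarks: a classification
#' counts as correct when the true label ranks within the k highest
#' probabilities. Monotone in `k` and consistent with [label_rank()] by
#' construction.
#'
#' @inheritParams label_rank
#' @param k cutoff, `1 <= k <= K`.
#' @return logical.
#' @export
in_topk <- function(probs, label, k = 5L, vocabulary = names(probs)) {
  K <- length(probs)
  if (k < 1 || k > K) stop("k must be in [1, K]")
  label_rank(probs, label, vocabulary) <= k
}

#' Chance-level probability for a K-way vocabulary
#'
#' The probability an uninformed classifier assigns any one label: exactly
#' `1/K` (0.1% for the 1000-category vocabularies of ImageNet-scale
#' networks).
#'
#' @param K vocabulary size (>= 1).
#' @export
chance_level <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1) stop("K must be >= 1")
  1 / K
}

#' Shape versus texture preference on a cue-conflict stimulus
#'
#' Directly compares the probability assigned to the label whose shape the
#' silhouette depicts with the probability of the label whose texture was
#' overlaid; whichever is strictly greater wins, equality is an explicit
#' `"tie"` (never split).
#'
#' @inheritParams label_rank
#' @param shape_label,texture_label the two conflicting labels (distinct).
#' @return `"shape"`, `"texture"`, or `"tie"`.
#' @export
shape_texture_preference <- function(probs, shape_label, texture_label,
                                     vocabulary = names(probs)) {
  if (identical(shape_label, texture_label))
    stop("shape and texture labels must be distinct")
  i <- match(shape_label, vocabulary)
  j <- match(texture_label, vocabulary)
  if (is.na(i) || is.na(j)) stop("labels must be in the vocabulary")
  p <- as.numeric(probs)
  if (p[i] > p[j]) "shape" else if (p[j] > p[i]) "texture" else "tie"
}

#' Compare a target label's probability to the mean of a comparison set
#'
#' Tests whether the probability given to the target label strictly exceeds
#' the average probability given to a set of other labels (e.g. the nine
#' other animal labels of the same superordinate group). Under an
#' exchangeable null the strict comparison succeeds about half the time.
#'
#' @inheritParams label_rank
#' @param target_label the label of interest.
#' @param other_labels nonempty set of comparison labels, excluding the
#'   target.
#' @return list with `higher` (logical, strict), `p_target`, `mean_others`.
#' @export
vs_class_mean <- function(probs, target_label, other_labels,
                          vocabulary = names(probs)) {
  if (!length(other_labels)) stop("other_labels must be nonempty")
  if (target_label %in% other_labels)
    stop("target label overlaps the comparison set")
  i <- match(target_label, vocabulary)
  j <- match(other_labels, vocabulary)
  if (is.na(i) || anyNA(j)) stop("labels must be in the vocabulary")
  p <- as.numeric(probs)
  list(higher = p[i] > mean(p[j]), p_target = p[i], mean_others = mean(p[j]))
}

#' One classification outcome
#'
#' Bundles a stimulus' provenance record with the probability vector a
#' classifier produced for it.
#'
#' @param record a [stimulus_record()].
#' @param probs named probability vector over `vocabulary`.
#' @param vocabulary the label vocabulary.
#' @export
classification_outcome <- function(record, probs, vocabulary = names(probs)) {
  if (!record$shape_label %in% vocabulary)
    stop("record shape_label not in vocabulary")
  if (!is.null(record$texture_label) && !record$texture_label %in% vocabulary)
    stop("record texture_label not in vocabulary")
  structure(list(record = record, probs = as.numeric(probs),
                 vocabulary = vocabulary),
            class = "classification_outcome")
}

#' Summarize classification outcomes per group
#'
#' Aggregates a set of outcomes into the per-group statistics of a
#' silhouette/chimera report: top-1 and top-5 correct counts (by shape
#' label), mean shape-label rank, mean probability assigned to the shape
#' (and, for chimeras, texture) label, the count of shape probabilities
#' below chance (`1/K`), and shape-versus-texture preference counts. When
#' exactly two groups are present the ratio of their mean shape
#' probabilities (first over second, in factor order) is attached as
#' `ratio_of_means`.
#'
#' @param outcomes list of [classification_outcome()]s.
#' @param groups character/factor of group labels, one per outcome (e.g.
#'   animal/artifact or manipulation condition).
#' @param k_top top-k cutoff for the "in top k" count.
#' @return a `summary_table`: data.frame with one row per group plus the
#'   `ratio_of_means` attribute; empty groups are dropped with a warning.
#' @export
summarize_outcomes <- function(outcomes, groups = rep("all", length(outcomes)),
                               k_top = 5L) {
  if (!length(outcomes)) stop("no outcomes to summarize")
  groups <- factor(groups)
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0L)) {
    warning("empty group(s) omitted: ",
            paste(levels(groups)[tabulate(groups, nbins = nlevels(groups)) == 0L],
                  collapse = ", "))
    groups <- droplevels(groups)
  }
  per_row <- lapply(outcomes, function(o) {
    K <- length(o$vocabulary)
    rk <- label_rank(o$probs, o$record$shape_label, o$vocabulary)
    p_shape <- o$probs[match(o$record$shape_label, o$vocabulary)]
    has_tex <- !is.null(o$record$texture_label)
    p_tex <- if (has_tex) o$probs[match(o$record$texture_label, o$vocabulary)] else NA_real_
    pref <- if (has_tex)
      shape_texture_preference(o$probs, o$record$shape_label,
                               o$record$texture_label, o$vocabulary)
    else NA_character_
    data.frame(rank = rk, top1 = rk == 1L, topk = rk <= k_top,
               p_shape = p_shape, p_texture = p_tex,
               below_chance = p_shape < chance_level(K), pref = pref,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, per_row)
  tab <- do.call(rbind, lapply(levels(groups), function(g) {
    d <- df[groups == g, , drop = FALSE]
    data.frame(group = g, n = nrow(d),
               n_top1_correct = sum(d$top1), n_top5_correct = sum(d$topk),
               mean_rank = mean(d$rank), mean_prob_shape = mean(d$p_shape),
               mean_prob_texture = mean(d$p_texture),
               n_below_chance = sum(d$below_chance),
               n_prefer_shape = sum(d$pref == "shape", na.rm = TRUE),
               n_prefer_texture = sum(d$pref == "texture", na.rm = TRUE),
               n_tie = sum(d$pref == "tie", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (nrow(tab) == 2L)
    attr(tab, "ratio_of_means") <- tab$mean_prob_shape[1] / tab$mean_prob_shape[2]
  class(tab) <- c("summary_table", "data.frame")
  tab
}

#' @export
print.summary_table <- function(x, ...) {
  print.data.frame(x, ...)
  r <- attr(x, "ratio_of_means")
  if (!is.null(r))
    cat(sprintf("ratio of mean shape probabilities (%s / %s): %.3f\n",
                x$group[1], x$group[2], r))
  invisible(x)
}

#' Human psychophysics responses
#'
#' One row per (subject, item, condition, display time) with a logical
#' `correct`; duplicates of that key are invalid.
#'
#' @param subject,item,condition,display_time,correct vectors of equal
#'   length; `condition` in scrambled/serrated/unscrambled, `display_time`
#'   in `"1s"`/`"unlimited"`.
#' @return a validated data.frame of class `human_responses`.
#' @export
human_responses <- function(subject, item, condition, display_time, correct) {
  condition <- match.arg(condition, c("scrambled", "serrated", "unscrambled"),
                         several.ok = TRUE)
  display_time <- match.arg(display_time, c("1s", "unlimited"), several.ok = TRUE)
  df <- data.frame(subject = subject, item = item, condition = condition,
                   display_time = display_time, correct = as.logical(correct),
                   stringsAsFactors = FALSE)
  key <- with(df, paste(subject, item, condition, display_time, sep = "\r"))
  if (anyDuplicated(key)) stop("duplicate (subject, item, condition, display_time) responses")
  class(df) <- c("human_responses", "data.frame")
  df
}

#' Score human recognition responses
#'
#' Per-item proportion correct within each (condition, display time) cell,
#' and per-condition means computed as the unweighted mean over items -- the
#' convention under which a printed condition mean equals the mean of its
#' item column.
#'
#' @param responses a [human_responses()] data.frame (or coercible).
#' @return list with `per_item` (item, condition, display_time, n,
#'   prop_correct) and `per_condition` (condition, display_time, n_items,
#'   mean_accuracy).
#' @export
score_human <- function(responses) {
  df <- if (inherits(responses, "human_responses")) responses
  else human_responses(responses$subject, responses$item, responses$condition,
                       responses$display_time, responses$correct)
  per_item <- stats::aggregate(correct ~ item + condition + display_time,
                               data = df,
                               FUN = function(x) mean(x))
  names(per_item)[names(per_item) == "correct"] <- "prop_correct"
  n_i <- stats::aggregate(correct ~ item + condition + display_time, data = df,
                          FUN = length)
  per_item$n <- n_i$correct
  per_cond <- stats::aggregate(prop_correct ~ condition + display_time,
                               data = per_item, FUN = mean)
  names(per_cond)[names(per_cond) == "prop_correct"] <- "mean_accuracy"
  n_items <- stats::aggregate(prop_correct ~ condition + display_time,
                              data = per_item, FUN = length)
  per_cond$n_items <- n_items$prop_correct
  list(per_item = per_item, per_condition = per_cond)
}

#' Pooled two-sample t test on per-subject accuracies
#'
#' Student's pooled-variance two-sample t test (`df = n1 + n2 - 2`),
#' two-sided -- the form implied when two groups of 10 subjects are compared
#' on 18 degrees of freedom. Delegates to `stats::t.test(var.equal = TRUE)`;
#' the degenerate zero-variance case with equal means returns `t = 0, p = 1`,
#' and with unequal means is an error.
#'
#' @param a,b numeric vectors of per-subject accuracies (each length >= 2).
#' @return list with `t`, `df`, `p` of class `t_test_result`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 subjects")
  df <- length(a) + length(b) - 2L
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(t = 0, df = df, p = 1), class = "t_test_result"))
    stop("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4f\n", x$df, x$t, x$p))
  invisible(x)
}

#' Write classification outcomes as a report table
#'
#' One row per stimulus mirroring the familiar top-five report layout:
#' item id, shape label and its probability, texture label and probability
#' (chimeras), the top five labels with probabilities, and correctness
#' flags.
#'
#' @param outcomes list of [classification_outcome()]s.
#' @param path optional CSV path; a `.json` twin is written alongside.
#' @return the report data.frame (invisibly if `path` given).
#' @export
outcome_table <- function(outcomes, path = NULL) {
  rows <- lapply(outcomes, function(o) {
    ord <- order(o$probs, decreasing = TRUE)[1:min(5L, length(o$probs))]
    rk <- label_rank(o$probs, o$record$shape_label, o$vocabulary)
    has_tex <- !is.null(o$record$texture_label)
    data.frame(
      item_id = o$record$item_id, manipulation = o$record$manipulation,
      shape_label = o$record$shape_label,
      p_shape = o$probs[match(o$record$shape_label, o$vocabulary)],
      texture_label = if (has_tex) o$record$texture_label else NA_character_,
      p_texture = if (has_tex) o$probs[match(o$record$texture_label, o$vocabulary)] else NA_real_,
      rank_shape = rk, top1_correct = rk == 1L, top5_correct = rk <= 5L,
      top5_labels = paste(o$vocabulary[ord], collapse = ";"),
      top5_probs = paste(signif(o$probs[ord], 6), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    jsonlite::write_json(tab, sub("\\.csv$", ".json", path), digits = NA)
    return(invisible(tab))
  }
  tab
}
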