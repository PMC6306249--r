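#' Experiment configuration
#'
#' A run is fully described by: which stimulus family to test
#' (`experiment`), where the shapes come from (`catalog`: parameters for
#' [build_catalog()]), which classifier to audit (`classifier`: a toy
#' feature kind or an adapter function), manipulation parameters, and a
#' mandatory seed. Configs can be given as R lists or YAML/JSON files.
#'
#' @param experiment one of `"silhouette"`, `"silhouette_colorways"`,
#'   `"outline"`, `"chimera"`, `"scramble"`, `"serrate"`.
#' @param catalog list of [build_catalog()] arguments (`C`, `E`, `seed`,
#'   `blob_fraction`, `canvas`, `r0`); the catalog seed defaults to the run
#'   seed.
#' @param classifier `"curvature_histogram"`, `"efd"`, or an adapter
#'   function `f(pixels) -> named probability vector` (see
#'   [external_adapter_contract()]).
#' @param params manipulation parameters (e.g. `n_parts`, `amplitude_px`,
#'   `period_px`, `stroke_px`).
#' @param seed run seed (mandatory).
#' @param out_dir optional output directory; when set, stimuli (PNG),
#'   tables (CSV/JSON) and the config echo are written there.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(experiment = c("silhouette", "silhouette_colorways",
                                             "outline", "chimera", "scramble",
                                             "serrate"),
                              catalog = list(C = 10L, E = 20L),
                              classifier = "efd", params = list(),
                              seed = NULL, out_dir = NULL) {
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(experiment = match.arg(experiment), catalog = catalog,
                 classifier = classifier, params = params,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML or JSON config file.
#' @export
read_experiment_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, cfg)
}

toy_kinds <- c("curvature_histogram", "efd")

# assign each class a signature texture; chimera overlays use the texture of
# the *next* class (a derangement), so shape and texture labels conflict
class_texture <- function(class_idx, n_classes) {
  kinds <- c("grating", "checkerboard", "dots")
  texture_spec(kind = kinds[(class_idx - 1L) %% 3L + 1L],
               period = 8 + 4 * ((class_idx - 1L) %/% 3L),
               orientation = pi * class_idx / n_classes,
               seed = 1000L + class_idx)
}

build_stimuli <- function(cat, config) {
  test <- catalog_split(cat, "test")
  vocab <- cat$vocabulary
  C <- length(vocab)
  prm <- config$params
  canvas <- cat$canvas
  stim <- list(); cond <- character(0)
  add <- function(s, cn) {
    stim[[length(stim) + 1L]] <<- s
    cond[length(cond) + 1L] <<- cn
  }
  for (i in seq_len(nrow(test))) {
    msk <- test$mask[[i]]
    lab <- test$class[i]
    iid <- sprintf("%s_e%02d", lab, test$exemplar[i])
    item_seed <- derive_seed(config$seed, i)
    switch(config$experiment,
      silhouette = add(render_silhouette(msk, out_size = canvas, record =
        stimulus_record(lab, "silhouette", colorway = standard_colorways("black_on_white"),
                        item_id = iid)), "silhouette"),
      silhouette_colorways = for (cw in names(standard_colorways())) {
        add(render_silhouette(msk, standard_colorways(cw), canvas, record =
          stimulus_record(lab, "silhouette", colorway = standard_colorways(cw),
                          params = list(colorway = cw),
                          item_id = paste(iid, cw, sep = "_"))), cw)
      },
      outline = add(render_outline(msk, prm$stroke_px %||% 2L, canvas, record =
        stimulus_record(lab, "outline", params = list(stroke_px = prm$stroke_px %||% 2L),
                        item_id = iid)), "outline"),
      chimera = {
        ci <- match(lab, vocab)
        tex_class <- vocab[ci %% C + 1L]
        tex <- gen_texture(class_texture(match(tex_class, vocab), C), canvas)
        add(render_texture_chimera(msk, tex, canvas, record =
          stimulus_record(lab, "chimera", texture_label = tex_class,
                          item_id = iid)), "chimera")
      },
      scramble = {
        placed <- place_mask(msk, canvas)
        add(render_silhouette(placed, out_size = canvas, place = FALSE, record =
          stimulus_record(lab, "silhouette", item_id = iid)), "unscrambled")
        sc <- part_scramble(placed, prm$n_parts %||% 4L, seed = item_seed,
                            report = FALSE)
        add(render_silhouette(sc$mask, out_size = canvas, place = FALSE, record =
          stimulus_record(lab, "part_scramble",
                          params = list(n_parts = prm$n_parts %||% 4L),
                          seed = item_seed, item_id = iid)), "scrambled")
      },
      serrate = {
        placed <- place_mask(msk, canvas)
        add(render_silhouette(placed, out_size = canvas, place = FALSE, record =
          stimulus_record(lab, "silhouette", item_id = iid)), "unperturbed")
        sr <- serrate(placed, prm$amplitude_px, prm$period_px, report = FALSE)
        add(render_silhouette(sr$mask, out_size = canvas, place = FALSE, record =
          stimulus_record(lab, "serrate", params = sr$params,
                          item_id = iid)), "serrated")
      })
  }
  list(stimuli = stim, condition = cond)
}

#' Run a complete audit experiment
#'
#' Generates the catalog, fits the requested toy classifier on the training
#' split (or takes the supplied adapter as-is), renders the experiment's
#' stimulus family for every held-out test exemplar, classifies each
#' stimulus, and aggregates the outcomes per condition. Deterministic given
#' the config (toy classifiers); the config echo in the report suffices to
#' reproduce the run.
#'
#' @param config an [experiment_config()] or a path to a YAML/JSON config.
#' @return a `run_report`: list with `manifest` (one row per stimulus),
#'   `outcomes` (one [classification_outcome()] per manifest row),
#'   `summaries` (a `summary_table` by condition), `config`, and `version`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  cat_args <- config$catalog
  cat_args$seed <- cat_args$seed %||% config$seed
  cat <- do.call(build_catalog, cat_args)
  classify <- make_classifier(config, cat)
  st <- build_stimuli(cat, config)
  outcomes <- lapply(st$stimuli, function(s) {
    p <- classify(s)
    v <- validate_probs(p, names(p))
    if (!v$ok) stop("classifier violated the probability contract: ",
                    paste(v$problems, collapse = "; "))
    if (!s$record$shape_label %in% names(p))
      stop("manifest-join error: label '", s$record$shape_label,
           "' missing from classifier vocabulary")
    classification_outcome(s$record, p)
  })
  manifest <- data.frame(
    item_id = vapply(st$stimuli, function(s) s$record$item_id, character(1)),
    shape_label = vapply(st$stimuli, function(s) s$record$shape_label, character(1)),
    manipulation = vapply(st$stimuli, function(s) s$record$manipulation, character(1)),
    condition = st$condition, stringsAsFactors = FALSE)
  report <- structure(
    list(manifest = manifest, outcomes = outcomes,
         summaries = summarize_outcomes(outcomes, st$condition),
         config = config,
         version = as.character(utils::packageVersion("shapecue"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, st$stimuli, config$out_dir)
  report
}

make_classifier <- function(config, cat) {
  if (is.function(config$classifier)) {
    adapter <- config$classifier
    return(function(s) adapter(s$pixels))
  }
  kind <- match.arg(config$classifier, toy_kinds)
  train <- catalog_split(cat, "train")
  # train at presentation scale: curvature (rad/px) is size-specific
  placed <- lapply(train$mask, place_mask, out_size = cat$canvas)
  model <- fit_toy(placed, train$class, feature_kind = kind)
  function(s) predict_toy(model, s)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report: %s, %d stimuli, seed %d>\n",
              x$config$experiment, nrow(x$manifest), x$config$seed))
  print(x$summaries)
  invisible(x)
}

write_run_report <- function(report, stimuli, out_dir) {
  dir.create(file.path(out_dir, "stimuli"), recursive = TRUE, showWarnings = FALSE)
  for (s in stimuli)
    write_stimulus_png(s, file.path(out_dir, "stimuli",
                                    paste0(s$record$item_id, "_",
                                           s$record$manipulation, ".png")))
  utils::write.csv(report$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  outcome_table(report$outcomes, file.path(out_dir, "outcomes.csv"))
  utils::write.csv(as.data.frame(report$summaries),
                   file.path(out_dir, "summary.csv"), row.names = FALSE)
  cfg <- report$config
  cfg$classifier <- if (is.function(cfg$classifier)) "external_adapter" else cfg$classifier
  jsonlite::write_json(list(config = unclass(cfg), version = report$version),
                       file.path(out_dir, "run.json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(out_dir)
}

#' Compare two runs item by item
#'
#' For every item present in both reports, the ratio of the probability each
#' run's classifier assigned to the correct (shape) label -- the
#' ratio-of-probabilities format used to compare unperturbed, scrambled and
#' serrated versions of the same objects. Ratios are reported per item
#' (log-scale-ready) together with their mean and the ratio of mean
#' probabilities.
#'
#' @param report_a,report_b `run_report`s over the same vocabulary and item
#'   set (matched on `item_id`).
#' @return list with `per_item` (data.frame: item_id, p_a, p_b, ratio),
#'   `mean_ratio`, `ratio_of_means`.
#' @export
compare_runs <- function(report_a, report_b) {
  pa <- shape_probs(report_a); pb <- shape_probs(report_b)
  if (!setequal(names(pa), names(pb)))
    stop("item sets differ between the two reports")
  va <- report_a$outcomes[[1]]$vocabulary
  vb <- report_b$outcomes[[1]]$vocabulary
  if (!identical(va, vb)) stop("vocabularies differ between the two reports")
  pb <- pb[names(pa)]
  per_item <- data.frame(item_id = names(pa), p_a = unname(pa),
                         p_b = unname(pb), ratio = unname(pa / pb),
                         stringsAsFactors = FALSE)
  list(per_item = per_item, mean_ratio = mean(per_item$ratio),
       ratio_of_means = mean(pa) / mean(pb))
}

#' Restrict a run report to one condition
#'
#' Conditions within one run (e.g. unscrambled vs scrambled) share item ids;
#' subset before [compare_runs()].
#'
#' @param report a `run_report`.
#' @param condition condition name from the report's manifest.
#' @return a `run_report` containing only that condition's stimuli.
#' @export
filter_report <- function(report, condition) {
  keep <- report$manifest$condition == condition
  if (!any(keep)) stop("no stimuli in condition '", condition, "'")
  out <- report
  out$manifest <- report$manifest[keep, , drop = FALSE]
  out$outcomes <- report$outcomes[keep]
  out$summaries <- summarize_outcomes(out$outcomes, out$manifest$condition)
  out
}

shape_probs <- function(report) {
  p <- vapply(report$outcomes, function(o)
    o$probs[match(o$record$shape_label, o$vocabulary)], numeric(1))
  names(p) <- vapply(report$outcomes, function(o) o$record$item_id, character(1))
  if (anyDuplicated(names(p)))
    stop("duplicate item ids; compare conditions from separate runs")
  p
}
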