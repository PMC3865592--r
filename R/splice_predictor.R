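# Splice-site loss prediction by consensus of three transparent scoring
# models over fixed donor/acceptor windows:
#   wmm          - position weight matrix (0-order log-odds vs uniform bg)
#   wam          - weight array model (1st-order Markov log-odds)
#   consensus_ic - information-content-weighted consensus match score
# Raw log-odds are min-max normalized over each model's attainable score
# range, so every method reports on a common [0,1] scale. A site is
# "recognized" when its normalized score reaches the recognition threshold;
# a variant is called a donor/acceptor loss only when ALL three methods
# recognize the wild-type window and none recognizes the mutant.

BASES <- c("A", "C", "G", "T")

seq_mat <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("training error: ragged sequence lengths")
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  if (any(!m %in% BASES)) stop("training error: non-ACGT base in training set")
  m
}

#' Train a splice-site scoring model
#'
#' @param seqs Character vector (>= 2) of aligned site windows, equal
#'   length, alphabet ACGT, in transcript orientation.
#' @param kind `"donor"` or `"acceptor"`.
#' @param method `"wmm"`, `"wam"` or `"consensus_ic"`.
#' @param pseudocount Additive smoothing count per base.
#' @param exonic,intronic Window geometry (exonic/intronic base counts);
#'   their sum must equal the training sequence length.
#' @return Object of class `sv_splice_model`.
#' @export
train_splice_model <- function(seqs, kind = c("donor", "acceptor"),
                               method = c("wmm", "wam", "consensus_ic"),
                               pseudocount = 0.1,
                               exonic = if (kind == "donor") 3L else 3L,
                               intronic = if (kind == "donor") 6L else 20L) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (length(seqs) < 2L) stop("training error: need at least 2 sequences")
  m <- seq_mat(seqs)
  L <- ncol(m)
  if (L != exonic + intronic) {
    stop("training error: sequence length ", L,
         " does not match geometry ", exonic, "+", intronic)
  }
  prob <- sapply(seq_len(L), function(j) {
    cnt <- table(factor(m[, j], levels = BASES))
    (as.numeric(cnt) + pseudocount) / (nrow(m) + 4 * pseudocount)
  })
  rownames(prob) <- BASES
  model <- list(kind = kind, method = method, length = L,
                exonic = as.integer(exonic), intronic = as.integer(intronic),
                pseudocount = pseudocount, background = 0.25, prob = prob)
  if (method == "wam") {
    cond <- lapply(seq_len(L - 1L), function(j) {
      cnt <- table(factor(m[, j], levels = BASES),
                   factor(m[, j + 1L], levels = BASES))
      p <- (unclass(cnt) + pseudocount) /
        (rowSums(unclass(cnt)) + 4 * pseudocount)
      dimnames(p) <- list(BASES, BASES)
      p
    })
    model$cond <- cond
  } else if (method == "consensus_ic") {
    ic <- apply(prob, 2, function(p) 2 + sum(p * log2(p)))
    model$ic <- ic
    model$modal <- BASES[apply(prob, 2, which.max)]
  }
  model$range <- attainable_range(model)
  structure(model, class = "sv_splice_model")
}

#' @export
print.sv_splice_model <- function(x, ...) {
  cat("<sv_splice_model> ", x$kind, "/", x$method, ", window ",
      x$exonic, "+", x$intronic, "\n", sep = "")
  invisible(x)
}

# attainable [min, max] of the raw score, for min-max normalization
attainable_range <- function(model) {
  lo <- function(p) log(p / model$background)
  if (model$method == "wmm") {
    cols <- lo(model$prob)
    c(sum(apply(cols, 2, min)), sum(apply(cols, 2, max)))
  } else if (model$method == "wam") {
    # forward DP over base states
    lo1 <- lo(model$prob[, 1])
    mn <- lo1; mx <- lo1
    for (j in seq_along(model$cond)) {
      step <- lo(model$cond[[j]])
      mn <- apply(step + mn, 2, min)
      mx <- apply(step + mx, 2, max)
    }
    c(min(mn), max(mx))
  } else {
    c(0, sum(model$ic))
  }
}

raw_score <- function(model, chars) {
  lo <- function(p) log(p / model$background)
  if (model$method == "consensus_ic") {
    return(sum(model$ic[chars == model$modal]))
  }
  isN <- !chars %in% BASES
  if (model$method == "wmm") {
    s <- 0
    for (j in seq_len(model$length)) {
      if (!isN[j]) s <- s + lo(model$prob[chars[j], j])
    }
    s
  } else {
    s <- if (isN[1]) 0 else lo(model$prob[chars[1], 1])
    for (j in seq_len(model$length - 1L)) {
      if (!isN[j] && !isN[j + 1L]) {
        s <- s + lo(model$cond[[j]][chars[j], chars[j + 1L]])
      }
    }
    s
  }
}

#' Score a site window under a trained model
#'
#' Raw log-odds against a uniform background, min-max normalized over the
#' model's attainable score range to `[0, 1]` (clipped). `N` bases score as
#' background.
#'
#' @param model An `sv_splice_model`.
#' @param window Character scalar, length matching the model geometry, in
#'   transcript orientation.
#' @return Normalized score in `[0, 1]`.
#' @export
score_site <- function(model, window) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(chars) != model$length) {
    stop("window length ", length(chars),
         " does not match model geometry (", model$length, ")")
  }
  if (any(!chars %in% c(BASES, "N"))) stop("window contains non-ACGTN base")
  r <- model$range
  s <- (raw_score(model, chars) - r[1]) / (r[2] - r[1])
  min(1, max(0, s))
}

#' Predictor parameters
#'
#' @param recognition_threshold Normalized score at or above which a site
#'   counts as recognized.
#' @param probability_threshold Threshold on the combined loss probability;
#'   applied as a hard filter only when `apply_probability_threshold`.
#' @param apply_probability_threshold Require the combined probability to
#'   exceed `probability_threshold` for a consensus loss call.
#' @return List of class `sv_predictor_params`.
#' @export
predictor_params <- function(recognition_threshold = 0.9,
                             probability_threshold = 0.9,
                             apply_probability_threshold = FALSE) {
  stopifnot(recognition_threshold >= 0, recognition_threshold <= 1,
            probability_threshold >= 0, probability_threshold <= 1)
  structure(list(recognition_threshold = recognition_threshold,
                 probability_threshold = probability_threshold,
                 apply_probability_threshold = apply_probability_threshold),
            class = "sv_predictor_params")
}

#' Default bundled splice-site models
#'
#' Trains the three scoring methods on the built-in canonical donor and
#' acceptor training windows.
#'
#' @param pseudocount Additive smoothing count.
#' @return Nested list: `$donor` / `$acceptor`, each holding `wmm`, `wam`,
#'   `consensus_ic` models.
#' @export
default_splice_models <- function(pseudocount = 0.1) {
  methods <- c("wmm", "wam", "consensus_ic")
  list(
    donor = stats::setNames(lapply(methods, function(m) {
      train_splice_model(DONOR_TRAINING, "donor", m, pseudocount)
    }), methods),
    acceptor = stats::setNames(lapply(methods, function(m) {
      train_splice_model(ACCEPTOR_TRAINING, "acceptor", m, pseudocount)
    }), methods)
  )
}

#' Predict splice-site loss for one wild-type/mutant window pair
#'
#' Scores both windows under every model; the constitutive site is lost
#' (effect `donor_lost`/`acceptor_lost`) only when all methods recognize
#' the wild type and none recognizes the mutant. The combined probability
#' is `1 - prod(mut_score / wt_score)` with per-method ratios clipped to
#' `[0, 1]` — monotone in the score drop, on `[0, 1]`, and not comparable
#' to any external classifier's probability.
#'
#' @param wt_window,mut_window Site windows (transcript orientation),
#'   identical geometry, differing at the variant base(s).
#' @param models Named list of models for the relevant side (e.g.
#'   `default_splice_models()$donor`).
#' @param params [predictor_params()].
#' @return List of class `sv_splice_prediction`: per-method scores and
#'   recognition flags, `effect`, `consensus`, `probability`.
#' @export
predict_splice_loss <- function(wt_window, mut_window, models,
                                params = predictor_params()) {
  if (identical(toupper(wt_window), toupper(mut_window))) {
    stop("no-variant error: wild-type and mutant windows are identical")
  }
  kinds <- unique(vapply(models, `[[`, "", "kind"))
  if (length(kinds) != 1L) stop("models mix donor and acceptor kinds")
  thr <- params$recognition_threshold
  per <- lapply(models, function(m) {
    wt <- score_site(m, wt_window)
    mut <- score_site(m, mut_window)
    list(wt_score = wt, mut_score = mut,
         wt_recognized = wt >= thr, mut_recognized = mut >= thr)
  })
  consensus <- all(vapply(per, function(x) {
    x$wt_recognized && !x$mut_recognized
  }, NA))
  ratios <- vapply(per, function(x) {
    if (x$wt_score <= 0) 1 else min(1, max(0, x$mut_score / x$wt_score))
  }, 0)
  probability <- min(1, max(0, 1 - prod(ratios)))
  lost <- consensus &&
    (!params$apply_probability_threshold ||
       probability > params$probability_threshold)
  effect <- if (lost) paste0(kinds, "_lost") else "none"
  structure(list(methods = per, effect = effect,
                 consensus = consensus && lost, probability = probability),
            class = "sv_splice_prediction")
}

#' @export
print.sv_splice_prediction <- function(x, ...) {
  for (m in names(x$methods)) {
    p <- x$methods[[m]]
    cat(sprintf("  %-12s wt %.3f%s / mut %.3f%s\n", m,
                p$wt_score, if (p$wt_recognized) "" else " (-)",
                p$mut_score, if (p$mut_recognized) "" else " (-)"))
  }
  cat("  effect: ", x$effect, "  probability: ",
      sprintf("%.3f", x$probability), "\n", sep = "")
  invisible(x)
}

# window geometry of a model set (all methods share geometry)
models_geometry <- function(models) {
  m <- models[[1]]
  list(exonic = m$exonic, intronic = m$intronic)
}

# position (1-based, transcript orientation) of an intronic offset inside a
# donor/acceptor window; NA when the offset falls outside the window
window_index_of_offset <- function(side, offset, geom) {
  if (side == "donor") {
    if (offset >= 1L && offset <= geom$intronic) geom$exonic + offset
    else NA_integer_
  } else {
    if (offset <= -1L && offset >= -geom$intronic) geom$intronic + 1L + offset
    else NA_integer_
  }
}

#' Batch splice-loss prediction over annotated variants
#'
#' For every `splicing` annotation, extracts the wild-type window at the
#' mutated boundary in transcript orientation, substitutes the
#' (strand-corrected) alternate base, and scores with the side-matched
#' models. Variants whose intronic offset falls outside the scored window
#' geometry are reported unevaluated (`in_window = FALSE`, effect `none`).
#'
#' @param annotations Annotation `data.frame` ([classify_variants()]).
#' @param genome An `sv_genome`.
#' @param transcripts Transcript list.
#' @param models [default_splice_models()]-shaped model list.
#' @param params [predictor_params()].
#' @return `data.frame`: one row per splicing annotation with per-method
#'   wt/mut scores, recognition flags, `effect`, `consensus`, `probability`.
#' @export
batch_predict <- function(annotations, genome, transcripts,
                          models = default_splice_models(),
                          params = predictor_params()) {
  sp <- annotations[annotations$region == "splicing", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sp))) {
    a <- sp[i, , drop = FALSE]
    tx <- transcripts[[a$transcript_id]]
    if (is.null(tx)) stop("unknown transcript in annotation: ",
                          a$transcript_id)
    side_models <- models[[a$side]]
    geom <- models_geometry(side_models)
    wt <- boundary_window(
      genome, tx,
      list(kind = a$side, genomic_position = a$boundary_position),
      donor_exonic = if (a$side == "donor") geom$exonic else 3L,
      donor_intronic = if (a$side == "donor") geom$intronic else 6L,
      acceptor_intronic = if (a$side == "acceptor") geom$intronic else 20L,
      acceptor_exonic = if (a$side == "acceptor") geom$exonic else 3L)
    idx <- window_index_of_offset(a$side, a$offset, geom)
    base <- data.frame(a, in_window = !is.na(idx), stringsAsFactors = FALSE)
    if (is.na(idx)) {
      rows[[length(rows) + 1L]] <- cbind(base, prediction_cols(NULL, models = side_models))
      next
    }
    alt <- if (tx$strand == "-") complement_base(a$alt_base) else a$alt_base
    mut <- wt
    substr(mut, idx, idx) <- alt
    pred <- predict_splice_loss(wt, mut, side_models, params)
    rows[[length(rows) + 1L]] <- cbind(base, prediction_cols(pred, side_models))
  }
  if (!length(rows)) {
    return(cbind(sp, in_window = logical(0),
                 prediction_cols(NULL, models$donor)[0, , drop = FALSE]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

prediction_cols <- function(pred, models) {
  cols <- list()
  for (m in names(models)) {
    p <- if (is.null(pred)) {
      list(wt_score = NA_real_, mut_score = NA_real_,
           wt_recognized = NA, mut_recognized = NA)
    } else pred$methods[[m]]
    cols[[paste0(m, "_wt")]] <- p$wt_score
    cols[[paste0(m, "_mut")]] <- p$mut_score
    cols[[paste0(m, "_wt_recognized")]] <- p$wt_recognized
    cols[[paste0(m, "_mut_recognized")]] <- p$mut_recognized
  }
  cols$effect <- if (is.null(pred)) "none" else pred$effect
  cols$consensus <- if (is.null(pred)) FALSE else pred$consensus
  cols$probability <- if (is.null(pred)) NA_real_ else pred$probability
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write a prediction report TSV
#'
#' Method scores are printed as `wt/mut` with `-` in place of an
#' unrecognized site score.
#'
#' @param predictions Output of [batch_predict()].
#' @param path Output path.
#' @export
write_predictions_tsv <- function(predictions, path) {
  fmt <- function(score, recognized) {
    ifelse(is.na(score), "NA",
           ifelse(recognized, sprintf("%.3f", score), "-"))
  }
  out <- data.frame(
    hgvs_c = predictions$hgvs_c,
    transcript_id = predictions$transcript_id,
    side = predictions$side, offset = predictions$offset,
    stringsAsFactors = FALSE)
  for (m in c("wmm", "wam", "consensus_ic")) {
    out[[m]] <- if (!nrow(out)) character(0) else paste0(
      fmt(predictions[[paste0(m, "_wt")]],
          predictions[[paste0(m, "_wt_recognized")]]),
      "/",
      fmt(predictions[[paste0(m, "_mut")]],
          predictions[[paste0(m, "_mut_recognized")]]))
  }
  out$effect <- predictions$effect
  out$probability <- round(predictions$probability, 3)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- model serialization ---------------------------------------------------

#' Serialize trained models to JSON
#' @param models Model list (as from [default_splice_models()]).
#' @param path Output JSON path.
#' @export
write_splice_models <- function(models, path) {
  ser <- lapply(models, function(side) {
    lapply(side, function(m) {
      u <- unclass(m)
      u$prob <- as.data.frame(u$prob)
      if (!is.null(u$cond)) u$cond <- lapply(u$cond, as.data.frame)
      u
    })
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load models serialized by [write_splice_models()]
#' @param path JSON path.
#' @return Model list.
#' @export
read_splice_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(side) {
    lapply(side, function(m) {
      m$prob <- as.matrix(m$prob)
      rownames(m$prob) <- BASES
      if (!is.null(m$cond)) {
        m$cond <- lapply(m$cond, function(cm) {
          cm <- as.matrix(cm); dimnames(cm) <- list(BASES, BASES); cm
        })
      }
      if (!is.null(m$modal)) m$modal <- as.character(m$modal)
      m$range <- as.numeric(m$range)
      structure(m, class = "sv_splice_model")
    })
  })
}
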