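# Corpus I/O: JSONL pair records and parallel plain-text files, plus the
# corpus-level evaluation report.

#' Read a paired corpus
#'
#' JSONL mode: one JSON object per line with fields `source`,
#' `reference`, optional `generated` and `id` (ids are auto-assigned
#' from the zero-padded line index when absent). Parallel mode: `path`
#' is the source file; the reference file (and optionally a generated
#' file) are separate line-aligned plain-text files.
#'
#' @param path JSONL file, or source text file in parallel mode.
#' @param format `"jsonl"` or `"parallel"`.
#' @param reference_path,generated_path Companion files for parallel
#'   mode.
#' @return List of `paragraph_pair`s in file order.
#' @export
read_pairs <- function(path, format = c("jsonl", "parallel"),
                       reference_path = NULL, generated_path = NULL) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      stop(sprintf("read_pairs(): '%s' contains no records", path),
           call. = FALSE)
    }
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop(sprintf("read_pairs(): malformed JSON on line %d of '%s': %s",
                                     i, path, conditionMessage(e)),
                             call. = FALSE)
                      })
      for (f in c("source", "reference")) {
        if (is.null(rec[[f]]) || !nzchar(rec[[f]])) {
          stop(sprintf("read_pairs(): line %d of '%s' is missing field '%s'",
                       i, path, f), call. = FALSE)
        }
      }
      out[[i]] <- paragraph_pair(
        id = rec$id %||% sprintf("%06d", i - 1L),
        source_text = rec$source, reference_text = rec$reference,
        generated_text = rec$generated
      )
    }
  } else {
    if (is.null(reference_path)) {
      stop("read_pairs(): parallel format needs reference_path",
           call. = FALSE)
    }
    src <- readLines(path, encoding = "UTF-8", warn = FALSE)
    ref <- readLines(reference_path, encoding = "UTF-8", warn = FALSE)
    gen <- if (!is.null(generated_path)) {
      readLines(generated_path, encoding = "UTF-8", warn = FALSE)
    }
    if (length(src) == 0L) {
      stop("read_pairs(): empty source file", call. = FALSE)
    }
    if (length(src) != length(ref) ||
        (!is.null(gen) && length(gen) != length(src))) {
      stop(sprintf("read_pairs(): line counts differ (source %d, reference %d%s)",
                   length(src), length(ref),
                   if (is.null(gen)) "" else sprintf(", generated %d", length(gen))),
           call. = FALSE)
    }
    out <- lapply(seq_along(src), function(i) {
      paragraph_pair(sprintf("%06d", i - 1L), src[i], ref[i],
                     if (!is.null(gen)) gen[i])
    })
  }
  ids <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("read_pairs(): duplicate ids in file", call. = FALSE)
  }
  out
}

#' Write a paired corpus as JSONL
#'
#' One record per line with fields `id`, `source`, `reference` and, when
#' present, `generated`. A round trip through [read_pairs()] restores
#' the same records.
#'
#' @param pairs List of `paragraph_pair`s.
#' @param path Output file.
#' @export
write_pairs <- function(pairs, path) {
  lines <- vapply(pairs, function(p) {
    rec <- list(id = p$id, source = p$source_text,
                reference = p$reference_text)
    if (!is.null(p$generated_text)) rec$generated <- p$generated_text
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Evaluate a paired corpus
#'
#' Produces the corpus-report layout used for simplification systems:
#' per-side readability means (FKGL and ARI of source and reference and,
#' when present, generated text), mean ROUGE-1/2 F1 and SARI of the
#' generated text against the single reference, mean rewards of the
#' generated text, and a Zipf-shift summary — each mean with its n,
#' alongside an echo of the configuration that produced it.
#'
#' @param pairs Non-empty list of `paragraph_pair`s.
#' @param lexicon A `freq_lexicon` for the lexical statistics.
#' @param weights A `reward_weights`.
#' @param embedder An `embedding_model`.
#' @param coefficients FKGL preset; see [fkgl_coefficients()].
#' @param saturation Lexical-ramp saturation.
#' @param readability_only If `TRUE`, skip generation metrics even if no
#'   pair has generated text.
#' @return An object of class `evaluation_report` (nested list; see
#'   `print` method).
#' @export
evaluate_pairs <- function(pairs, lexicon,
                           weights = reward_weights(),
                           embedder = hashed_bow_embedder(),
                           coefficients = "standard",
                           saturation = 0.4,
                           readability_only = FALSE) {
  if (length(pairs) == 0L) stop("evaluate_pairs(): no pairs", call. = FALSE)
  has_gen <- vapply(pairs, function(p) !is.null(p$generated_text) &&
                      nzchar(p$generated_text), logical(1))
  if (!readability_only && !any(has_gen)) {
    stop("evaluate_pairs(): no pair has generated text; use readability_only",
         call. = FALSE)
  }
  fk <- function(txt) fkgl(analyze_text(txt), coefficients)
  ar <- function(txt) ari(analyze_text(txt))
  src_fk <- vapply(pairs, function(p) fk(p$source_text), numeric(1))
  src_ar <- vapply(pairs, function(p) ar(p$source_text), numeric(1))
  ref_fk <- vapply(pairs, function(p) fk(p$reference_text), numeric(1))
  ref_ar <- vapply(pairs, function(p) ar(p$reference_text), numeric(1))
  dz <- vapply(pairs, function(p)
    lexical_stats(p$source_text, p$reference_text, lexicon)$delta_z,
    numeric(1))
  report <- list(
    n = length(pairs),
    readability = list(
      source = list(fkgl = mean(src_fk), ari = mean(src_ar),
                    n = length(pairs)),
      reference = list(fkgl = mean(ref_fk), ari = mean(ref_ar),
                       n = length(pairs))
    ),
    delta_z = list(mean = mean(dz), sd = stats::sd(dz), n = length(pairs)),
    config = list(
      fkgl_preset = if (is.character(coefficients)) coefficients else "custom",
      weights = unclass(weights), saturation = saturation,
      embedder = embedder$name,
      lexicon_words = length(lexicon$table), oov_zipf = lexicon$oov_zipf
    )
  )
  if (any(has_gen)) {
    gp <- pairs[has_gen]
    cfg <- reward_config(lexicon, weights, embedder, coefficients,
                         saturation)
    gen_fk <- vapply(gp, function(p) fk(p$generated_text), numeric(1))
    gen_ar <- vapply(gp, function(p) ar(p$generated_text), numeric(1))
    r1 <- vapply(gp, function(p)
      rouge_n(p$generated_text, p$reference_text, 1L)[["f1"]], numeric(1))
    r2 <- vapply(gp, function(p)
      rouge_n(p$generated_text, p$reference_text, 2L)[["f1"]], numeric(1))
    sa <- vapply(gp, function(p)
      sari(p$source_text, p$generated_text, p$reference_text), numeric(1))
    bds <- lapply(gp, function(p)
      score_generation(p$source_text, p$reference_text, p$generated_text,
                       cfg))
    mean_of <- function(f) mean(vapply(bds, `[[`, numeric(1), f))
    report$generation <- list(
      n = length(gp),
      readability = list(fkgl = mean(gen_fk), ari = mean(gen_ar)),
      rouge1_f1 = mean(r1), rouge2_f1 = mean(r2), sari = mean(sa),
      rewards = list(r_cosine = mean_of("r_cosine"),
                     r_flesch = mean_of("r_flesch"),
                     r_lexical = mean_of("r_lexical"),
                     total = mean_of("total"))
    )
  }
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation over %d pairs\n", x$n))
  cat(sprintf("  readability (FKGL / ARI, preset '%s')\n",
              x$config$fkgl_preset))
  cat(sprintf("    source     %6.2f / %6.2f\n",
              x$readability$source$fkgl, x$readability$source$ari))
  cat(sprintf("    reference  %6.2f / %6.2f\n",
              x$readability$reference$fkgl, x$readability$reference$ari))
  if (!is.null(x$generation)) {
    g <- x$generation
    cat(sprintf("    generated  %6.2f / %6.2f   (n = %d)\n",
                g$readability$fkgl, g$readability$ari, g$n))
    cat(sprintf("  ROUGE-1 F1 %.4f | ROUGE-2 F1 %.4f | SARI %.4f\n",
                g$rouge1_f1, g$rouge2_f1, g$sari))
    cat(sprintf("  rewards: cosine %.4f, flesch %.4f, lexical %.4f, total %.4f\n",
                g$rewards$r_cosine, g$rewards$r_flesch,
                g$rewards$r_lexical, g$rewards$total))
  }
  cat(sprintf("  delta_z mean %.3f (sd %.3f)\n",
              x$delta_z$mean, x$delta_z$sd))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
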