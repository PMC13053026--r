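round_cols <- function() {
  c("round_index", "is_practice", "target", "sent_u", "sent_v", "guess",
    "correct", "duration_s")
}

validate_rounds <- function(r, dyad_id, refs = referents()) {
  where <- function(i) paste0("dyad ", dyad_id, ", row ", i)
  missing <- setdiff(round_cols(), names(r))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(diff(r$round_index) <= 0)) {
    i <- which(diff(r$round_index) <= 0)[1] + 1
    stop("non-monotone round indices at ", where(i))
  }
  bad <- which(!r$target %in% refs)
  if (length(bad)) {
    stop("unknown target '", r$target[bad[1]], "' at ", where(bad[1]))
  }
  bad <- which(!is.na(r$guess) & !r$guess %in% refs)
  if (length(bad)) {
    stop("unknown guess '", r$guess[bad[1]], "' at ", where(bad[1]))
  }
  ok <- !is.na(r$guess) & r$guess == r$target
  if (any(r$correct != ok)) {
    i <- which(r$correct != ok)[1]
    stop("correct flag inconsistent with guess/target at ", where(i))
  }
  if (any(r$duration_s <= 0)) {
    stop("non-positive duration at ",
         where(which(r$duration_s <= 0)[1]))
  }
  invisible(TRUE)
}

infer_won <- function(rounds) {
  main <- rounds[!rounds$is_practice, , drop = FALSE]
  if (nrow(main) == 0) return(FALSE)
  lg <- new_game_log("tmp", "low", rounds, won = FALSE)
  es <- established_series(lg, include_practice = FALSE)
  es$s[nrow(es)] == 6 && main$correct[nrow(main)]
}

logs_to_flat <- function(logs) {
  if (inherits(logs, "game_log")) logs <- list(logs)
  rows <- lapply(logs, function(g) {
    r <- g$rounds
    cbind(tibble::tibble(dyad_id = g$dyad_id, condition = g$condition,
                         won = g$won), r)
  })
  do.call(rbind, rows)
}

flat_to_logs <- function(flat, condition_levels) {
  stopifnot(all(c("dyad_id", "condition") %in% names(flat)))
  bad <- which(!flat$condition %in% condition_levels)
  if (length(bad)) {
    stop("unknown condition label '", flat$condition[bad[1]], "' at row ",
         bad[1])
  }
  ids <- unique(flat$dyad_id)
  lapply(ids, function(id) {
    d <- flat[flat$dyad_id == id, , drop = FALSE]
    extra <- setdiff(names(d), c("dyad_id", "condition", "won", round_cols()))
    r <- tibble::as_tibble(d[, c(round_cols(), extra), drop = FALSE])
    validate_rounds(r, id)
    won <- if ("won" %in% names(d)) isTRUE(d$won[1]) else infer_won(r)
    new_game_log(id, d$condition[1], r, won)
  })
}

num_chr <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}

#' Write game logs to disk
#'
#' Serializes logs in one of two plain-text dialects. JSON Lines is the
#' canonical dialect: per dyad, one header record
#' (`{"record":"dyad", dyad_id, condition, won, total_time_s}`) followed by
#' one record per round. CSV is the flat interchange dialect: one row per
#' round with the dyad columns repeated, numerics printed at full precision.
#' Both round-trip losslessly through [read_logs()].
#'
#' @param logs A `game_log` or list of them.
#' @param path Output file path.
#' @param format `"jsonl"` or `"csv"`; inferred from the file extension by
#'   default.
#' @return `path`, invisibly.
#' @export
write_logs <- function(logs, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "jsonl"
  }
  if (inherits(logs, "game_log")) logs <- list(logs)
  if (format == "jsonl") {
    lines <- unlist(lapply(logs, function(g) {
      head <- jsonlite::toJSON(
        list(record = "dyad", dyad_id = g$dyad_id, condition = g$condition,
             won = g$won, total_time_s = g$total_time_s),
        auto_unbox = TRUE, digits = NA, na = "null")
      body <- vapply(seq_len(nrow(g$rounds)), function(i) {
        row <- as.list(g$rounds[i, round_cols()])
        jsonlite::toJSON(c(list(record = "round"), row),
                         auto_unbox = TRUE, digits = NA, na = "null")
      }, character(1))
      c(head, body)
    }))
    writeLines(lines, path)
  } else {
    flat <- logs_to_flat(logs)
    for (col in c("sent_u", "sent_v", "duration_s")) {
      flat[[col]] <- num_chr(flat[[col]])
    }
    utils::write.csv(flat, path, row.names = FALSE, quote = FALSE,
                     na = "")
  }
  invisible(path)
}

#' Read game logs from disk
#'
#' Parses either dialect written by [write_logs()], validating the schema as
#' it goes: required columns, strictly increasing round indices per dyad,
#' known condition and referent labels, and consistency of the `correct`
#' flag. Violations raise errors naming the offending dyad and row. A
#' missing `won` flag (possible in external CSVs) is inferred by re-scoring
#' the main rounds.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`; inferred from the extension by
#'   default.
#' @param condition_levels Permitted condition labels.
#' @return A list of `game_log` objects.
#' @export
read_logs <- function(path, format = c("auto", "jsonl", "csv"),
                      condition_levels = c(conditions(),
                                           "followup_color_log",
                                           "followup_color_nolog",
                                           "followup_dot_log",
                                           "followup_dot_nolog")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path)
    recs <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i]),
               error = function(e) stop("line ", i, ": malformed JSON (",
                                        conditionMessage(e), ")"))
    })
    kinds <- vapply(recs, function(x) x$record %||% "", character(1))
    if (!length(recs) || kinds[1] != "dyad") {
      stop("line 1: expected a dyad header record")
    }
    starts <- which(kinds == "dyad")
    ends <- c(starts[-1] - 1, length(recs))
    logs <- lapply(seq_along(starts), function(k) {
      head <- recs[[starts[k]]]
      body <- recs[seq(starts[k] + 1, length.out = ends[k] - starts[k])]
      if (!length(body)) stop("dyad ", head$dyad_id, " has no rounds")
      r <- tibble::as_tibble(do.call(rbind, lapply(body, function(x) {
        data.frame(
          round_index = as.integer(x$round_index),
          is_practice = isTRUE(x$is_practice),
          target = as.character(x$target),
          sent_u = if (is.null(x$sent_u)) NA_real_ else as.numeric(x$sent_u),
          sent_v = if (is.null(x$sent_v)) NA_real_ else as.numeric(x$sent_v),
          guess = if (is.null(x$guess)) NA_character_ else
            as.character(x$guess),
          correct = isTRUE(x$correct),
          duration_s = as.numeric(x$duration_s)
        )
      })))
      validate_rounds(r, head$dyad_id)
      if (!head$condition %in% condition_levels) {
        stop("unknown condition label '", head$condition, "' for dyad ",
             head$dyad_id)
      }
      new_game_log(head$dyad_id, head$condition, r, isTRUE(head$won))
    })
    logs
  } else {
    flat <- utils::read.csv(path, stringsAsFactors = FALSE)
    if ("guess" %in% names(flat)) {
      flat$guess <- ifelse(flat$guess == "" | is.na(flat$guess),
                           NA_character_, flat$guess)
    }
    missing <- setdiff(round_cols(), names(flat))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
    flat_to_logs(flat, condition_levels)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adapt an externally deposited round table
#'
#' Maps a flat CSV of game rounds with arbitrary column names and condition
#' labels into the package's log schema via a user-supplied mapping, then
#' validates it exactly as [read_logs()] would. The deposited-data layout is
#' not hard-coded anywhere: the mapping carries it. Columns not mentioned in
#' the mapping are preserved on each log's rounds table.
#'
#' @param path CSV file path.
#' @param mapping List with `columns` (named character vector: canonical
#'   name -> column name in the file; identity for names omitted) and
#'   optionally `condition_labels` (named character vector: file label ->
#'   canonical condition label).
#' @return A list of `game_log` objects.
#' @export
#' @examples
#' \donttest{
#' f <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(c(high = 1, low = 1), seed = 3)
#' write_logs(cohort, f)
#' identical_logs <- adapt_deposited(f, mapping = list())
#' }
adapt_deposited <- function(path, mapping = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  colmap <- mapping$columns %||% character(0)
  canonical <- c("dyad_id", "condition", "won", round_cols())
  for (nm in names(colmap)) {
    if (!nm %in% canonical) stop("unknown canonical column in mapping: ", nm)
    src <- colmap[[nm]]
    if (!src %in% names(flat)) {
      stop("mapped column '", src, "' for '", nm,
           "' not found; file has: ", paste(names(flat), collapse = ", "))
    }
    names(flat)[names(flat) == src] <- nm
  }
  required <- c("dyad_id", "condition", round_cols())
  missing <- setdiff(required, names(flat))
  if (length(missing)) {
    stop("unmapped required field(s): ", paste(missing, collapse = ", "),
         "; candidate columns in file: ",
         paste(setdiff(names(flat), required), collapse = ", "))
  }
  if (!is.null(mapping$condition_labels)) {
    lab <- mapping$condition_labels
    known <- flat$condition %in% names(lab)
    flat$condition[known] <- unname(lab[flat$condition[known]])
  }
  if ("guess" %in% names(flat)) {
    flat$guess <- ifelse(flat$guess == "" | is.na(flat$guess),
                         NA_character_, flat$guess)
  }
  flat_to_logs(flat, conditions())
}
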