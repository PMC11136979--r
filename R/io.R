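# Deterministic full-precision number formatting: 17 significant digits
# round-trip IEEE doubles exactly, so write -> read is lossless and output
# bytes are reproducible.
.fmt <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17, format = "g"))
}

.write_meta <- function(con, meta) {
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.null(v)) next
    if (is.numeric(v)) v <- paste(.fmt(v), collapse = ",")
    writeLines(sprintf("# %s=%s", k, paste(v, collapse = ",")), con)
  }
}

.read_meta <- function(lines) {
  ml <- grep("^#", lines, value = TRUE)
  ml <- sub("^#\\s*", "", ml)
  kv <- regmatches(ml, regexpr("=", ml), invert = TRUE)
  meta <- lapply(kv, function(p) if (length(p) == 2L) p[2L] else "")
  names(meta) <- vapply(kv, `[`, character(1L), 1L)
  meta
}

.check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " is missing required column '", miss[1L], "'")
}

#' Write / read a raw MINFLUX trace table
#'
#' Tab-separated long format, one row per axis per cycle, with columns
#' \code{t_s}, \code{axis}, \code{L_nm}, \code{center_nm}, \code{n_minus},
#' \code{n_0}, \code{n_plus}, \code{est_nm}, \code{valid}.  Metadata are
#' preserved verbatim in leading \code{# key=value} lines.  Numeric columns
#' round-trip losslessly (17 significant digits).
#'
#' @param trace a \code{"raw_trace"}.
#' @param path file path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns a \code{"raw_trace"}.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(trace, "metadata")
  cfg <- attr(trace, "beam_config")
  if (!is.null(cfg))
    meta <- c(meta, cfg[c("L_schedule", "exposure_us", "switch_dead_us",
                          "recalc_dead_ns", "brightness", "background")])
  .write_meta(con, meta)
  writeLines(paste(c("t_s", "axis", "L_nm", "center_nm", "n_minus", "n_0",
                     "n_plus", "est_nm", "valid"), collapse = "\t"), con)
  n <- nrow(trace)
  long <- data.frame(
    t_s = rep(trace$t, each = 2L),
    axis = rep(c("x", "y"), n),
    L_nm = rep(trace$L, each = 2L),
    center_nm = as.vector(rbind(trace$center_x, trace$center_y)),
    n_minus = as.vector(rbind(trace$n_minus_x, trace$n_minus_y)),
    n_0 = as.vector(rbind(trace$n_0_x, trace$n_0_y)),
    n_plus = as.vector(rbind(trace$n_plus_x, trace$n_plus_y)),
    est_nm = as.vector(rbind(trace$est_x, trace$est_y)),
    valid = as.integer(as.vector(rbind(trace$valid_x, trace$valid_y))))
  lines <- sprintf("%s\t%s\t%s\t%s\t%d\t%d\t%d\t%s\t%d",
                   .fmt(long$t_s), long$axis, .fmt(long$L_nm),
                   .fmt(long$center_nm), long$n_minus, long$n_0, long$n_plus,
                   .fmt(long$est_nm), long$valid)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_columns(df, c("t_s", "axis", "L_nm", "center_nm", "n_minus", "n_0",
                       "n_plus", "est_nm", "valid"), "trace table")
  xs <- df[df$axis == "x", , drop = FALSE]
  ys <- df[df$axis == "y", , drop = FALSE]
  if (nrow(xs) != nrow(ys)) stop("trace table has unpaired x/y rows")
  out <- data.frame(t = as.numeric(xs$t_s), L = as.numeric(xs$L_nm),
                    center_x = as.numeric(xs$center_nm),
                    n_minus_x = as.integer(xs$n_minus),
                    n_0_x = as.integer(xs$n_0),
                    n_plus_x = as.integer(xs$n_plus),
                    est_x = as.numeric(xs$est_nm), valid_x = xs$valid == 1,
                    center_y = as.numeric(ys$center_nm),
                    n_minus_y = as.integer(ys$n_minus),
                    n_0_y = as.integer(ys$n_0),
                    n_plus_y = as.integer(ys$n_plus),
                    est_y = as.numeric(ys$est_nm), valid_y = ys$valid == 1)
  out$valid <- out$valid_x & out$valid_y
  structure(out, class = c("raw_trace", "data.frame"), metadata = meta)
}

#' Write / read a step-fit table
#'
#' Tab-separated, one row per plateau: \code{segment_index},
#' \code{t_start_s}, \code{t_end_s}, \code{level_on_nm},
#' \code{level_off_nm}, \code{step_to_next_on_nm},
#' \code{step_to_next_off_nm}, \code{dwell_s} and, if states are supplied,
#' a \code{state} column (B/U).
#'
#' @param fit a \code{"step_fit"}.
#' @param path file path.
#' @param states optional \code{"state_sequence"} to annotate.
#' @return \code{write_steps} returns \code{path} invisibly;
#'   \code{read_steps} returns a \code{"step_fit"} (with a
#'   \code{"states"} attribute if the table has a state column).
#' @export
write_steps <- function(fit, path, states = NULL) {
  stopifnot(inherits(fit, "step_fit"))
  K <- length(fit$levels_on)
  off <- if (is.null(fit$levels_off)) rep(NA_real_, K) else fit$levels_off
  son <- c(fit$steps_on, NA_real_)
  soff <- if (is.null(fit$steps_off)) rep(NA_real_, K) else c(fit$steps_off, NA_real_)
  cols <- c("segment_index", "t_start_s", "t_end_s", "level_on_nm",
            "level_off_nm", "step_to_next_on_nm", "step_to_next_off_nm",
            "dwell_s")
  lines <- sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   seq_len(K), .fmt(fit$t_start), .fmt(fit$t_end),
                   .fmt(fit$levels_on), .fmt(off), .fmt(son), .fmt(soff),
                   .fmt(fit$dwells))
  if (!is.null(states)) {
    stopifnot(length(states$labels) == K)
    cols <- c(cols, "state")
    lines <- paste(lines, states$labels, sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  .write_meta(con, list(n_samples = fit$n, sigma_nm = fit$sigma,
                        source = fit$source))
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_steps
#' @export
read_steps <- function(path) {
  lines <- readLines(path)
  meta <- .read_meta(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_columns(df, c("segment_index", "t_start_s", "t_end_s",
                       "level_on_nm", "level_off_nm", "step_to_next_on_nm",
                       "step_to_next_off_nm", "dwell_s"), "step table")
  K <- nrow(df)
  tc <- df$t_end_s[-K]
  fit <- new_step_fit(change_points = seq_len(max(K - 1L, 0L)),
                      t_change = tc, change_dt = rep(0, max(K - 1L, 0L)),
                      levels_on = df$level_on_nm,
                      levels_off = if (all(is.na(df$level_off_nm))) NULL
                                   else df$level_off_nm,
                      t_start = df$t_start_s, t_end = df$t_end_s,
                      n = as.integer(if (!is.null(meta$n_samples))
                        meta$n_samples else K),
                      sigma = as.numeric(if (!is.null(meta$sigma_nm))
                        meta$sigma_nm else NA),
                      source = if (!is.null(meta$source)) meta$source else "file")
  if (!is.null(df$state))
    attr(fit, "states") <- structure(list(labels = df$state, loglik = NA_real_),
                                     class = "state_sequence")
  fit
}

#' Write an analysis results list as JSON
#'
#' Scalars are written as bare JSON numbers at full precision.
#'
#' @param results a (possibly nested) list of results.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
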