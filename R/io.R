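TRIAL_COLUMNS <- c("trial", "d", "theta", "x_act", "x_conf", "x_new", "a",
                   "z_pre", "z_post", "correct")

#' Write a trial table to CSV
#'
#' Comma-separated, UTF-8, mandatory header
#' `trial,d,theta,x_act,x_conf,x_new,a,z_pre,z_post,correct`, `.` decimal
#' separator, floats at 12 significant digits, missing optionals (`x_new`,
#' `z_pre`, `z_post`) as empty fields.
#'
#' @param trials A `trial_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)[, TRIAL_COLUMNS]
  fmt <- function(x) {
    out <- trimws(formatC(x, digits = 12, format = "g"))
    out[is.na(x)] <- ""
    out
  }
  for (col in c("theta", "x_act", "x_conf", "x_new", "z_pre", "z_post"))
    df[[col]] <- fmt(df[[col]])
  df$correct <- ifelse(df$correct, "TRUE", "FALSE")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Reads the dialect written by [write_trial_table()] and validates the
#' invariants: the header must match exactly; actions must be consistent
#' with the decision rule (`a = +1` iff `x_act > 0`); `correct` must equal
#' `a == d`; any present confidence must lie in `[0, 1]`.
#'
#' @param path CSV file path.
#' @return A `trial_table`. An empty file with a valid header yields an
#'   empty table without error.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, TRIAL_COLUMNS)) {
    missing <- setdiff(TRIAL_COLUMNS, header)
    extra <- setdiff(header, TRIAL_COLUMNS)
    stop("trial-table header mismatch",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")) else "",
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")) else "",
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c(
    trial = "integer", d = "integer", theta = "numeric", x_act = "numeric",
    x_conf = "numeric", x_new = "numeric", a = "integer", z_pre = "numeric",
    z_post = "numeric", correct = "logical"), fileEncoding = "UTF-8")
  if (nrow(df) > 0) {
    bad_a <- which(df$a != ifelse(df$x_act > 0, 1L, -1L))
    if (length(bad_a))
      stop("decision-rule violation (a inconsistent with x_act) at rows: ",
           paste(utils::head(bad_a, 10), collapse = ", "), call. = FALSE)
    bad_c <- which(df$correct != (df$a == df$d))
    if (length(bad_c))
      stop("correctness flag inconsistent with a == d at rows: ",
           paste(utils::head(bad_c, 10), collapse = ", "), call. = FALSE)
    for (col in c("z_pre", "z_post")) {
      z <- df[[col]]
      bad_z <- which(!is.na(z) & (z < 0 | z > 1))
      if (length(bad_z))
        stop(col, " outside [0, 1] at rows: ",
             paste(utils::head(bad_z, 10), collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Generate the canonical fixture tables
#'
#' Writes one deterministic 2000-trial table per observer model at the
#' canonical parameters (`sigma_act = 1`, `sigma_conf = 1`, `rho = 0.6`,
#' `theta = 1`): `fixture_first_order.csv`, `fixture_postdecisional.csv`,
#' `fixture_second_order.csv`. Regeneration with the same seed is
#' byte-identical.
#'
#' @param seed Integer root seed.
#' @param dir Output directory (created if needed).
#' @param n Trials per fixture.
#' @return Named character vector of file paths, invisibly.
#' @export
generate_fixtures <- function(seed = 20170101L, dir = ".", n = 2000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  models <- c("first_order", "postdecisional", "second_order")
  paths <- character(0)
  for (i in seq_along(models)) {
    m <- models[i]
    tt <- simulate_trials(gen_params(1, 1, 0.6, 1), n = n,
                          belief = belief_params(m, 1, 1, 0.6),
                          seed = child_seed(seed, i))
    p <- file.path(dir, sprintf("fixture_%s.csv", m))
    write_trial_table(tt, p)
    paths[m] <- p
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records tool version, experiment id, the full parameter set, the root
#' seed and the child-seed scheme, timestamps, and an md5 digest for every
#' output file, as JSON. A run is reproducible from its manifest alone.
#'
#' @param path Manifest file path.
#' @param experiment_id Identifier of the run.
#' @param params Named list of all parameters.
#' @param seed Root seed.
#' @param outputs Character vector of files written by the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, experiment_id, params, seed, outputs) {
  digests <- if (length(outputs))
    as.list(tools::md5sum(outputs)) else list()
  manifest <- list(
    tool = "metaconf",
    version = as.character(utils::packageVersion("metaconf")),
    experiment_id = experiment_id,
    parameters = params,
    root_seed = seed,
    child_seed_scheme = "child_seed(root, stage) = (root %% 2147483647 + 1013904223 * stage) %% 2147483647",
    child_seeds = as.list(stats::setNames(
      vapply(seq_len(4), function(k) child_seed(seed, k), integer(1)),
      paste0("stage_", seq_len(4)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = digests,
    note = "grids and trial counts are package defaults; see documentation"
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest file path.
#' @return The manifest as a named list.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
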