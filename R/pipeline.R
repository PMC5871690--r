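## End-to-end session pipeline: validate -> rasterize -> states -> summaries
## -> joint/synchrony -> condition comparison -> event export.

#' Run the full analysis pipeline from a YAML config
#'
#' Config layout (YAML):
#' \preformatted{
#' fps: 30
#' output_dir: out
#' alpha: 0.05
#' min_duration_frames: 1
#' fill: {SM: 0}          # optional per-dimension gap fill
#' columns: {onset_s: start}  # optional column map for the input files
#' sessions:
#'   - dyad: d01
#'     condition: teaching
#'     file: d01_teaching.csv
#'   - ...
#' }
#' Per session it writes rasterized timelines, state sequences, summary
#' JSONs, the joint distribution CSV, a synchrony JSON and BIDS-events style
#' TSVs. When at least two dyads have the same two conditions, per-state
#' paired comparisons (condition 2 minus condition 1, BH-FDR across the 8
#' states) are written per participant group; otherwise the comparison stage
#' is skipped with a logged notice. A machine-readable run log (package
#' version, config hash, seed) completes the bundle. Any stage failure
#' aborts with the stage name and offending input.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param outputDir overrides the config's \code{output_dir}.
#' @param seed recorded in the run log and set before any stochastic stage
#'   (the pipeline itself is deterministic given its inputs).
#' @return Invisibly, a list with the per-session summaries and (when run)
#'   the comparison tables.
#' @export
runPipeline <- function(config, outputDir = NULL, seed = 1L) {
  configPath <- NULL
  if (is.character(config)) {
    configPath <- config
    if (!file.exists(config))
      stop("[stage config] config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  outdir <- if (!is.null(outputDir)) outputDir else config$output_dir
  if (is.null(outdir)) stop("[stage config] no output_dir configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fps <- if (is.null(config$fps)) 30 else config$fps
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  minDur <- if (is.null(config$min_duration_frames)) 1L
            else as.integer(config$min_duration_frames)
  fill <- if (is.null(config$fill)) NULL else unlist(config$fill)
  columns <- if (is.null(config$columns)) NULL else unlist(config$columns)
  if (is.null(config$sessions) || !length(config$sessions))
    stop("[stage config] no sessions configured")
  set.seed(seed)

  log <- list(package = "dyadplay",
              version = as.character(utils::packageVersion("dyadplay")),
              r_version = as.character(getRversion()),
              seed = seed, fps = fps, alpha = alpha,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config_hash = if (!is.null(configPath))
                unname(tools::md5sum(configPath)) else NA,
              sessions = list(), notices = character(0))

  summaries <- list()
  freqs <- list(infant = list(), adult = list())
  meta <- data.frame(dyad = character(0), condition = character(0))

  for (sess in config$sessions) {
    id <- paste(sess$dyad, sess$condition, sep = "_")
    sdir <- file.path(outdir, id)
    dir.create(sdir, showWarnings = FALSE)
    if (is.null(sess$file) || !file.exists(sess$file))
      stop(sprintf("[stage read, session %s] annotation file not found: %s",
                   id, if (is.null(sess$file)) "<unset>" else sess$file))
    ann <- tryCatch(
      readAnnotations(sess$file, columns = columns),
      error = function(e) stop(sprintf("[stage validate, session %s] %s",
                                       id, conditionMessage(e)), call. = FALSE))
    dyad <- tryCatch(
      rasterizeDyad(ann, fps = fps, fill = fill,
                    duration_s = sess$duration_s,
                    sessionId = sess$dyad, condition = sess$condition),
      error = function(e) stop(sprintf("[stage rasterize, session %s] %s",
                                       id, conditionMessage(e)), call. = FALSE))

    sessSummary <- list()
    for (who in c("infant", "adult")) {
      tl <- slot(dyad, who)
      writeTimeline(tl, file.path(sdir, paste0(who, "_timeline.tsv")))
      sq <- deriveStates(tl)
      writeStateSequence(sq, file.path(sdir, paste0(who, "_states.tsv")))
      sm <- stateSummary(tl)
      jsonlite::write_json(sm, file.path(sdir, paste0(who, "_summary.json")),
                           auto_unbox = TRUE, digits = NA)
      segs <- segmentStates(sq, minDuration = minDur)
      exportEvents(segs, fps = fps,
                   path = file.path(sdir, paste0(who, "_events.tsv")),
                   participant = who, sessionId = sess$dyad,
                   condition = sess$condition)
      freqs[[who]][[id]] <- sm$state_frequencies
      sessSummary[[who]] <- sm
    }
    jd <- jointDistribution(jointStates(dyad))
    utils::write.csv(jd, file.path(sdir, "joint_distribution.csv"))
    sy <- synchrony(jointStates(dyad))
    jsonlite::write_json(sy, file.path(sdir, "synchrony.json"),
                         auto_unbox = TRUE, digits = NA)
    sessSummary$synchrony <- sy
    summaries[[id]] <- sessSummary
    meta <- rbind(meta, data.frame(dyad = sess$dyad,
                                   condition = sess$condition))
    log$sessions[[id]] <- list(file = sess$file, n_frames = nFrames(dyad))
  }

  comparisons <- NULL
  conds <- unique(meta$condition)
  complete <- if (length(conds) == 2) {
    tab <- table(meta$dyad, meta$condition)
    rownames(tab)[rowSums(tab == 1) == 2]
  } else character(0)
  if (length(conds) == 2 && length(complete) >= 2) {
    comparisons <- list()
    for (who in c("infant", "adult")) {
      mats <- lapply(conds, function(cn) {
        m <- do.call(rbind, lapply(complete, function(dd)
          freqs[[who]][[paste(dd, cn, sep = "_")]]))
        rownames(m) <- complete
        m
      })
      cmp <- compareConditions(mats[[1]], mats[[2]], alpha = alpha)
      utils::write.table(
        cbind(participant = who, cmp),
        file.path(outdir, paste0("comparison_", who, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      comparisons[[who]] <- cmp
    }
    log$comparison <- sprintf("paired comparison of %s vs %s over %d dyads",
                              conds[2], conds[1], length(complete))
  } else {
    log$notices <- c(log$notices, sprintf(
      "comparison stage skipped: need >= 2 dyads with both of exactly 2 conditions (have %d condition(s), %d complete dyad(s))",
      length(conds), length(complete)))
    message(log$notices[length(log$notices)])
  }

  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summaries = summaries, comparisons = comparisons,
                 log = log))
}
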