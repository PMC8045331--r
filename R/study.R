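#' Analyze one case in all configured directions
#'
#' Runs the per-case analysis: computes (or accepts) the consensus CTV, then
#' for every configured direction the consensus margin
#' ([directionalMargin()] against the consensus CTV) and the margin
#' deviation ([marginDeviation()] against the individual expert CTVs),
#' recording ray-casting diagnostics. A failure in one direction is recorded
#' in that direction's row and does not abort the case.
#'
#' @param caseId character(1) case identifier.
#' @param gtv non-empty [BinaryVolume-class] GTV mask.
#' @param expertCtvs list of grid-compatible expert CTV masks (may be empty
#'   when \code{consensusCtv} is supplied; margin deviations then stay
#'   \code{NA}).
#' @param consensusCtv optional [BinaryVolume-class]; when \code{NULL} it is
#'   computed from the experts with [stapleConsensus()].
#' @param directions list of [DirectionSpec-class] (or labels / numeric(3)).
#' @param barrier optional [BinaryVolume-class] barrier mask.
#' @param control see [castControl()].
#' @param stapleThreshold posterior threshold for the computed consensus.
#' @return a [CaseResult-class].
#' @export
runCase <- function(caseId, gtv, expertCtvs = list(), consensusCtv = NULL,
                    directions, barrier = NULL, control = castControl(),
                    stapleThreshold = 0.5) {
  directions <- lapply(directions, asDirectionSpec)
  labels <- vapply(directions, directionLabel, character(1))
  if (anyDuplicated(labels))
    ctvStop("ctv_label_parse",
            sprintf("case %s: duplicate direction labels", caseId))
  if (length(directions) < 1L)
    ctvStop("ctv_label_parse",
            sprintf("case %s: at least one direction is required", caseId))
  if (is.null(consensusCtv)) {
    if (length(expertCtvs) == 0L)
      ctvStop("ctv_no_raters",
              sprintf("case %s: expert CTVs are required to compute a consensus", caseId))
    consensusCtv <- consensusMask(stapleConsensus(expertCtvs,
                                                  threshold = stapleThreshold))
  }
  details <- list()
  rows <- lapply(directions, function(ds) {
    lab <- directionLabel(ds)
    row <- data.frame(
      case_id = caseId, direction_label = lab, route_class = routeClass(ds),
      consensus_margin_mm = NA_real_, margin_cv = NA_real_,
      n_vectors = NA_integer_, n_rejected_interior = NA_integer_,
      n_rejected_barrier = NA_integer_, n_clamped = NA_integer_,
      status = "ok", message = "", stringsAsFactors = FALSE)
    res <- tryCatch(
      withCallingHandlers(
        directionalMargin(gtv, consensusCtv, ds, barrier, control),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- "failed"
      row$message <- conditionMessage(res)
      return(row)
    }
    vs <- expansionVectors(res)
    row$consensus_margin_mm <- marginMm(res)
    row$n_vectors <- length(vectorLengths(vs))
    row$n_rejected_interior <- vs@nRejectedInterior
    row$n_rejected_barrier <- vs@nRejectedBarrier
    row$n_clamped <- vs@nClamped
    details[[lab]] <<- list(margin = res)
    if (length(expertCtvs) >= 2L) {
      dev <- tryCatch(
        withCallingHandlers(
          marginDeviation(gtv, expertCtvs, ds, barrier, control),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) e)
      if (inherits(dev, "error")) {
        row$status <- "failed"
        row$message <- conditionMessage(dev)
      } else {
        row$margin_cv <- marginCV(dev)
        details[[lab]]$deviation <<- dev
      }
    }
    row
  })
  new("CaseResult", caseId = caseId, table = do.call(rbind, rows),
      details = details)
}

#' @rdname ctvMargins-accessors
#' @export
setMethod("caseTable", "CaseResult", function(object) object@table)

setMethod("show", "CaseResult", function(object) {
  cat(sprintf("Case \"%s\": %d direction(s)\n", object@caseId,
              nrow(object@table)))
  t <- object@table
  for (i in seq_len(nrow(t))) {
    if (t$status[i] == "ok")
      cat(sprintf("  %-6s [%s]: margin %.1f mm, CV %s\n",
                  t$direction_label[i], t$route_class[i],
                  t$consensus_margin_mm[i],
                  if (is.na(t$margin_cv[i])) "-" else
                    sprintf("%.2f", t$margin_cv[i])))
    else
      cat(sprintf("  %-6s [%s]: FAILED (%s)\n", t$direction_label[i],
                  t$route_class[i], t$message[i]))
  }
})

#' Summarize directional margins across cases by route class
#'
#' Pools every successfully evaluated direction across all cases under its
#' route-of-spread class (each direction contributes one datum; route
#' classes attach per direction, so one case can contribute to several
#' classes) and reports the median and (min, max) range of the consensus
#' margins and margin deviations per class. Failed directions are excluded
#' from the statistics and counted.
#'
#' @param results list of [CaseResult-class] objects.
#' @param routeClasses optional named character vector mapping direction
#'   labels to route classes, overriding the classes recorded per direction.
#' @return data.frame with one row per route class: \code{route_class},
#'   \code{n_cases}, \code{n_directions}, \code{n_failed},
#'   \code{median_margin_mm}, \code{min_margin_mm}, \code{max_margin_mm},
#'   \code{median_cv}, \code{min_cv}, \code{max_cv}.
#' @export
summarizeStudy <- function(results, routeClasses = NULL) {
  tab <- do.call(rbind, lapply(results, caseTable))
  if (!is.null(routeClasses)) {
    hit <- tab$direction_label %in% names(routeClasses)
    tab$route_class[hit] <- unname(routeClasses[tab$direction_label[hit]])
  }
  ok <- tab[tab$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0L)
    ctvStop("ctv_nothing_to_summarize",
            "no direction was evaluated successfully")
  out <- do.call(rbind, lapply(split(ok, ok$route_class), function(g) {
    failed <- sum(tab$route_class == g$route_class[1] & tab$status != "ok")
    cvs <- g$margin_cv[!is.na(g$margin_cv)]
    data.frame(
      route_class = g$route_class[1],
      n_cases = length(unique(g$case_id)),
      n_directions = nrow(g),
      n_failed = failed,
      median_margin_mm = stats::median(g$consensus_margin_mm),
      min_margin_mm = min(g$consensus_margin_mm),
      max_margin_mm = max(g$consensus_margin_mm),
      median_cv = if (length(cvs)) stats::median(cvs) else NA_real_,
      min_cv = if (length(cvs)) min(cvs) else NA_real_,
      max_cv = if (length(cvs)) max(cvs) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a study configuration
#'
#' Reads a YAML or JSON study configuration. The top level holds
#' \code{cases}, each with fields \code{case_id}, \code{gtv_path},
#' \code{expert_ctv_paths} (list), optional \code{consensus_ctv_path} and
#' \code{barrier_path}, and \code{directions}: a list of either
#' \code{\{label, route_class\}} (label parsed per [directionFromLabel()])
#' or \code{\{label, vector, route_class\}} with an explicit LPS vector.
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml}/\code{.json}).
#' @return a list of validated case configurations.
#' @seealso [runStudy()]
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path))
    ctvStop("ctv_io_error", sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  cases <- cfg$cases %||% cfg
  ids <- vapply(cases, function(cs) as.character(cs$case_id), character(1))
  if (anyDuplicated(ids))
    ctvStop("ctv_label_parse", "case_id values must be unique within a study")
  lapply(cases, function(cs) {
    if (is.null(cs$gtv_path) || length(cs$directions %||% list()) == 0L)
      ctvStop("ctv_label_parse",
              sprintf("case %s: gtv_path and at least one direction are required",
                      cs$case_id %||% "?"))
    list(
      case_id = as.character(cs$case_id),
      gtv_path = resolve(cs$gtv_path),
      consensus_ctv_path = resolve(cs$consensus_ctv_path),
      expert_ctv_paths = lapply(cs$expert_ctv_paths %||% list(), resolve),
      barrier_path = resolve(cs$barrier_path),
      directions = lapply(cs$directions, function(d) {
        if (!is.null(d$vector))
          DirectionSpec(d$label, vector = unlist(d$vector),
                        routeClass = d$route_class %||% "unspecified")
        else directionFromLabel(d$label,
                                routeClass = d$route_class %||% "unspecified")
      }))
  })
}

#' Run a full margin study
#'
#' Loads every case's masks, runs [runCase()] per case with per-direction
#' progress on stderr, summarizes with [summarizeStudy()], and (optionally)
#' writes the report files: one JSON per case, a study-level CSV with one
#' row per (case, direction), and a study summary JSON. Outputs are written
#' at full precision and are byte-identical across repeated runs on the same
#' inputs.
#'
#' @param config a configuration file path or the list returned by
#'   [readStudyConfig()].
#' @param outDir optional output directory for the report files.
#' @param control see [castControl()].
#' @param stapleThreshold posterior threshold for computed consensus CTVs.
#' @param quiet suppress progress messages.
#' @return list with elements \code{results} (list of [CaseResult-class])
#'   and \code{summary} (the [summarizeStudy()] data.frame), invisibly when
#'   \code{outDir} is given.
#' @export
runStudy <- function(config, outDir = NULL, control = castControl(),
                     stapleThreshold = 0.5, quiet = FALSE) {
  if (is.character(config)) config <- readStudyConfig(config)
  results <- lapply(config, function(cs) {
    if (!quiet)
      message(sprintf("case %s: loading masks", cs$case_id))
    gtv <- readMask(cs$gtv_path)
    experts <- lapply(cs$expert_ctv_paths, readMask)
    consensus <- if (!is.null(cs$consensus_ctv_path))
      readMask(cs$consensus_ctv_path) else NULL
    barrier <- if (!is.null(cs$barrier_path)) readMask(cs$barrier_path)
      else NULL
    if (!quiet)
      message(sprintf("case %s: %d direction(s), %d expert(s)", cs$case_id,
                      length(cs$directions), length(experts)))
    runCase(cs$case_id, gtv, experts, consensus, cs$directions, barrier,
            control, stapleThreshold)
  })
  summary <- summarizeStudy(results)
  out <- list(results = results, summary = summary)
  if (!is.null(outDir)) {
    writeStudyOutputs(results, summary, outDir)
    return(invisible(out))
  }
  out
}

#' Write study report files
#'
#' Writes \code{<case_id>.json} per case (per-direction results and
#' diagnostics), \code{study.csv} (one row per case and direction with the
#' columns \code{case_id}, \code{direction_label}, \code{route_class},
#' \code{consensus_margin_mm}, \code{margin_cv}, \code{n_vectors},
#' \code{n_rejected_interior}, \code{n_rejected_barrier}, \code{n_clamped},
#' \code{status}, \code{message}) and \code{summary.json}. All values are
#' written at full precision; rounding to the reporting precision (0.1 mm
#' margins, 0.01 CV) is left to presentation, as in the show methods.
#'
#' @param results list of [CaseResult-class].
#' @param summary the [summarizeStudy()] data.frame.
#' @param outDir output directory, created if needed.
#' @return \code{outDir}, invisibly.
#' @export
writeStudyOutputs <- function(results, summary, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (res in results) {
    jsonlite::write_json(
      list(case_id = res@caseId, per_direction = caseTable(res)),
      file.path(outDir, paste0(res@caseId, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null",
      pretty = TRUE)
  }
  tab <- do.call(rbind, lapply(results, caseTable))
  utils::write.csv(tab, file.path(outDir, "study.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(outDir)
}
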