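#' Questionnaire scoring
#'
#' Scoring for the three human-factors instruments used alongside the
#' balance protocol: the Simulator Sickness Questionnaire (SSQ, 16 symptoms
#' rated 0-3, three overlapping 7-item subscales with published weights),
#' the igroup Presence Questionnaire (iPQ, 14 items rated 1-5, one general
#' item plus spatial-presence/involvement/realism subscales), and the System
#' Usability Scale (SUS, 10 items rated 1-5, Brooke 0-100 composite). Item
#' maps and keying ship as editable YAML data assets under
#' `inst/extdata/` rather than being hard-coded.
#'
#' @name questionnaires
NULL

read_asset <- function(name) {
  path <- system.file("extdata", name, package = "posturo")
  if (path == "") stop("missing data asset: ", name)
  yaml::read_yaml(path)
}

#' @rdname questionnaires
#' @return `ssq_item_map()`, `ipq_item_map()`, `sus_item_map()` return the
#'   parsed YAML instrument definitions.
#' @export
ssq_item_map <- function() read_asset("ssq_items.yaml")

#' @rdname questionnaires
#' @export
ipq_item_map <- function() read_asset("ipq_items.yaml")

#' @rdname questionnaires
#' @export
sus_item_map <- function() read_asset("sus_items.yaml")

check_ratings <- function(ratings, n_items, range, instrument) {
  if (length(ratings) != n_items) {
    stop(sprintf("%s requires exactly %d item ratings, got %d",
                 instrument, n_items, length(ratings)))
  }
  bad <- which(!is.finite(ratings) | ratings < range[1] | ratings > range[2] |
                 ratings != round(ratings))
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid rating for item %d (value %s; allowed %d..%d)",
                 instrument, bad[1L], format(ratings[bad[1L]]),
                 range[1], range[2]))
  }
  invisible(TRUE)
}

#' Score a Simulator Sickness Questionnaire response
#'
#' Each subscale score is the raw sum of its 7 items times the published
#' weighting factor (9.54 nausea, 7.58 oculomotor, 13.92 disorientation);
#' items shared between subscales contribute to every subscale they belong
#' to. The total is the sum of the three *unweighted* raw subscale sums
#' times 3.74.
#'
#' @param ratings Integer vector of 16 symptom ratings in 0..3, in
#'   instrument item order.
#' @return Named list: `nausea`, `oculomotor`, `disorientation`, `total`.
#' @export
score_ssq <- function(ratings) {
  map <- ssq_item_map()
  check_ratings(ratings, length(map$items), unlist(map$rating_range), "SSQ")
  raw <- c(nausea = 0, oculomotor = 0, disorientation = 0)
  for (it in map$items) {
    for (sc in it$subscales) raw[[sc]] <- raw[[sc]] + ratings[it$id]
  }
  w <- map$weights
  list(
    nausea = raw[["nausea"]] * w$nausea,
    oculomotor = raw[["oculomotor"]] * w$oculomotor,
    disorientation = raw[["disorientation"]] * w$disorientation,
    total = sum(raw) * w$total
  )
}

#' Classify an SSQ total score
#'
#' A total strictly above 100 indicates the respondent is actively ill from
#' simulator sickness.
#'
#' @param total SSQ total score.
#' @return `"actively_ill"` or `"acceptable"`.
#' @export
classify_ssq <- function(total) {
  stopifnot(is.numeric(total), length(total) == 1L, is.finite(total))
  threshold <- ssq_item_map()$actively_ill_threshold
  if (total > threshold) "actively_ill" else "acceptable"
}

#' Score an igroup Presence Questionnaire response
#'
#' Reverse-keyed items are inverted (`min + max - rating`) before summing.
#' Returns the 14-item total (range 14-70 on the 1-5 scale; the neutral
#' reference is half the maximum, 35) and the general / spatial presence /
#' involvement / experienced-realism subscale sums.
#'
#' @param ratings Integer vector of 14 item ratings in 1..5, in instrument
#'   item order.
#' @return Named list: `total`, `general`, `spatial`, `involvement`,
#'   `realism`.
#' @export
score_ipq <- function(ratings) {
  map <- ipq_item_map()
  rng <- unlist(map$rating_range)
  check_ratings(ratings, length(map$items), rng, "iPQ")
  keyed <- ratings
  sums <- c(general = 0, spatial = 0, involvement = 0, realism = 0)
  for (it in map$items) {
    v <- if (isTRUE(it$reverse)) rng[1] + rng[2] - ratings[it$id]
         else ratings[it$id]
    keyed[it$id] <- v
    sums[[it$category]] <- sums[[it$category]] + v
  }
  c(list(total = sum(keyed)), as.list(sums))
}

#' Neutral-presence reference of the iPQ total scale
#'
#' Half the maximum achievable 14-item total under the implemented rating
#' range: 70/2 = 35 on the 1-5 scale. Computed from the item map, not
#' hard-coded.
#'
#' @return The neutral reference value (iPQ points).
#' @export
ipq_neutral_reference <- function() {
  map <- ipq_item_map()
  length(map$items) * unlist(map$rating_range)[2] / 2
}

#' Score a System Usability Scale response
#'
#' Brooke scoring: positively keyed (odd) items contribute `rating - 1`,
#' negatively keyed (even) items `5 - rating`; the sum of contributions is
#' scaled by 2.5 onto 0-100.
#'
#' @param ratings Integer vector of 10 item ratings in 1..5.
#' @return Composite usability score in `[0, 100]`.
#' @export
score_sus <- function(ratings) {
  map <- sus_item_map()
  rng <- unlist(map$rating_range)
  check_ratings(ratings, length(map$items), rng, "SUS")
  contrib <- vapply(map$items, function(it) {
    if (it$keying == "positive") ratings[it$id] - rng[1]
    else rng[2] - ratings[it$id]
  }, numeric(1))
  sum(contrib) * map$scale_factor
}

#' Score a long-format response table
#'
#' Batch scorer over a data.frame with columns
#' `participant,instrument,item,rating` (instrument one of `ssq`, `ipq`,
#' `sus`). Participants whose response vector fails validation are reported
#' in the `errors` element rather than aborting the batch.
#'
#' @param responses Long-format responses data.frame.
#' @return List with `scores` (data.frame
#'   `participant,instrument,scale,score`) and `errors` (data.frame
#'   `participant,instrument,message`).
#' @export
score_responses <- function(responses) {
  need <- c("participant", "instrument", "item", "rating")
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0L) {
    stop("responses table missing columns: ", paste(miss, collapse = ", "))
  }
  scorers <- list(
    ssq = function(r) score_ssq(r),
    ipq = function(r) score_ipq(r),
    sus = function(r) list(sus = score_sus(r))
  )
  scores <- list(); errors <- list()
  for (inst in intersect(names(scorers), unique(responses$instrument))) {
    di <- responses[responses$instrument == inst, , drop = FALSE]
    for (p in unique(di$participant)) {
      dp <- di[di$participant == p, , drop = FALSE]
      dp <- dp[order(dp$item), , drop = FALSE]
      res <- tryCatch(scorers[[inst]](dp$rating), error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <- data.frame(
          participant = p, instrument = inst,
          message = conditionMessage(res), row.names = NULL)
      } else {
        scores[[length(scores) + 1L]] <- data.frame(
          participant = p, instrument = inst,
          scale = names(res), score = unlist(res, use.names = FALSE),
          row.names = NULL)
      }
    }
  }
  list(
    scores = if (length(scores)) do.call(rbind, scores) else
      data.frame(participant = character(0), instrument = character(0),
                 scale = character(0), score = numeric(0)),
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(participant = character(0), instrument = character(0),
                 message = character(0))
  )
}
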