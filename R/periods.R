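#' Extract maximal stay-periods from raw RTLS records
#'
#' Consecutive grid records of one tag in the same zone merge into one period
#' with `st` = first timestamp and `et` = last timestamp + `sample_interval`
#' (half-open interval: a tag observed at an instant is credited with the full
#' sampling slot).  A zone change *or* a tracking gap (consecutive records
#' more than one sampling interval apart) closes the period; gaps are never
#' bridged.  Each party runs this locally on its own view before the joint
#' protocol.
#'
#' @param records data.frame with columns `tagID`, `tagRole`, `time`, `zID`;
#'   at most one record per (tag, time), all times on the sampling grid.
#' @param sample_interval sampling period in seconds.
#' @return data.frame `tagID, st, et, zID, tagRole`, sorted by tag then time,
#'   with attribute `role_scope` in `nurses_only` / `patients_only` / `mixed`.
#' @export
extract_periods <- function(records, sample_interval) {
  req <- c("tagID", "tagRole", "time", "zID")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("input-format error: missing column ", miss[1])
  dt <- as.integer(sample_interval)
  if (nrow(records) == 0) {
    out <- data.frame(tagID = character(), st = integer(), et = integer(),
                      zID = integer(), tagRole = character(),
                      stringsAsFactors = FALSE)
    attr(out, "role_scope") <- "mixed"
    return(out)
  }
  if (any(records$time %% dt != 0)) stop("input-format error: timestamps off the sampling grid")
  o <- order(records$tagID, records$time)
  r <- records[o, , drop = FALSE]
  if (anyDuplicated(paste(r$tagID, r$time, sep = "\r"))) {
    stop("input-format error: duplicate (tag, time) record")
  }
  new_tag <- c(TRUE, r$tagID[-1] != r$tagID[-nrow(r)])
  gap <- c(TRUE, diff(r$time) != dt)
  new_zone <- c(TRUE, r$zID[-1] != r$zID[-nrow(r)])
  grp <- cumsum(new_tag | gap | new_zone)
  first <- !duplicated(grp)
  last <- rev(!duplicated(rev(grp)))
  out <- data.frame(
    tagID = r$tagID[first],
    st = as.integer(r$time[first]),
    et = as.integer(r$time[last] + dt),
    zID = as.integer(r$zID[first]),
    tagRole = r$tagRole[first],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "role_scope") <- period_scope(out$tagRole)
  out
}

period_scope <- function(roles) {
  if (length(roles) == 0) return("mixed")
  nurse <- roles == "nurse"
  if (all(nurse)) "nurses_only" else if (!any(nurse)) "patients_only" else "mixed"
}

#' Expand a period table back to grid records
#'
#' Emits one record per tag per grid time inside each half-open period; on
#' dropout-free data this is the exact inverse of [extract_periods()].
#'
#' @param periods data.frame `tagID, st, et, zID, tagRole` with per-tag
#'   disjoint intervals on the sampling grid.
#' @param sample_interval sampling period in seconds.
#' @return data.frame `tagID, tagRole, time, zID` sorted by tag then time.
#' @export
periods_to_grid <- function(periods, sample_interval) {
  dt <- as.integer(sample_interval)
  if (nrow(periods) == 0) {
    return(data.frame(tagID = character(), tagRole = character(),
                      time = integer(), zID = integer(), stringsAsFactors = FALSE))
  }
  if (any(periods$st >= periods$et) ||
      any(periods$st %% dt != 0) || any(periods$et %% dt != 0)) {
    stop("invariant violation: periods must be non-empty half-open grid intervals")
  }
  o <- order(periods$tagID, periods$st)
  p <- periods[o, , drop = FALSE]
  same <- p$tagID[-1] == p$tagID[-nrow(p)]
  if (nrow(p) > 1 && any(same & p$st[-1] < p$et[-nrow(p)])) {
    stop("invariant violation: overlapping periods for one tag")
  }
  nrec <- (p$et - p$st) %/% dt
  idx <- rep.int(seq_len(nrow(p)), nrec)
  off <- (sequence(nrec) - 1L) * dt
  out <- data.frame(
    tagID = p$tagID[idx],
    tagRole = p$tagRole[idx],
    time = as.integer(p$st[idx] + off),
    zID = as.integer(p$zID[idx]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
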