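#' Duration bins for facing-time classification
#'
#' `boundaries` are the inner bin edges in seconds; bin `b` covers the
#' left-open right-closed interval `(boundaries[b-1], boundaries[b]]` and the
#' last bin is unbounded above.  The default `c(10, 30, 60)` yields the four
#' classes 0-10 s, 10-30 s, 30-60 s and > 60 s (a boundary value falls in the
#' lower bin).
#'
#' @param boundaries strictly increasing positive integers.
#' @return object of class `time_bins` with fields `boundaries`, `n_bins`,
#'   `labels`.
#' @export
time_bins <- function(boundaries = c(10, 30, 60)) {
  boundaries <- as.integer(boundaries)
  if (length(boundaries) > 0) {
    if (any(boundaries <= 0) || any(diff(boundaries) <= 0)) {
      stop("bin boundaries must be strictly increasing positive integers")
    }
  }
  nb <- length(boundaries) + 1L
  if (nb == 1L) labels <- ">0"
  else {
    lo <- c(0L, boundaries[-length(boundaries)])
    labels <- c(paste0(lo, "-", boundaries), paste0(">", boundaries[length(boundaries)]))
  }
  structure(list(boundaries = boundaries, n_bins = nb, labels = labels),
            class = "time_bins")
}

#' @export
print.time_bins <- function(x, ...) {
  cat("<time_bins>", x$n_bins, "bins:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Overlap between two half-open periods, in seconds
#'
#' `max(0, min(et1, et2) - max(st1, st2))`; touching intervals overlap by 0.
#' Zone agreement is deliberately not checked here.
#' @param st1,et1,st2,et2 numeric vectors (recycled).
#' @return numeric vector of overlaps.
#' @export
period_overlap <- function(st1, et1, st2, et2) {
  pmax(0, pmin(et1, et2) - pmax(st1, st2))
}

#' Duration bin of an overlap
#'
#' @param ov integer overlap(s) in seconds.
#' @param bins a [time_bins()].
#' @return integer bin index in `1..n_bins`, or `NA` for `ov <= 0`.
#' @export
overlap_bin <- function(ov, bins) {
  b <- bins$boundaries
  out <- if (length(b) == 0) rep(1L, length(ov)) else findInterval(ov - 0.5, b) + 1L
  out[ov <= 0] <- NA_integer_
  as.integer(out)
}

patient_type_of <- function(roles) {
  ok <- startsWith(roles, "patient:")
  if (!all(ok)) stop("input error: patient rows must carry role 'patient:<TYPE>'")
  sub("^patient:", "", roles)
}

#' Build the nurse-patient facing-time frequency table
#'
#' Iterates over all (nurse period, patient period) pairs; every pair in the
#' same zone with strictly positive overlap contributes exactly one count to
#' the cell addressed by the nurse, the patient's type and the overlap's
#' duration bin.  The counting unit is the period pair: a nurse re-entering a
#' patient's zone starts a new interaction.  Row `i` of the resulting count
#' matrix is the data point of nurse `i` for clustering.
#'
#' @param nurse_periods period table scoped to nurses.
#' @param patient_periods period table scoped to patients (roles
#'   `patient:<TYPE>`).
#' @param bins a [time_bins()].
#' @param nurse_ids ordered nurse identifiers (rows of the table); defaults
#'   to the sorted tags present.
#' @param type_labels ordered patient type labels (column blocks); defaults
#'   to the sorted types present.
#' @return object of class `facing_table`: integer count matrix
#'   `n_nurses x (n_types * n_bins)` plus layout metadata.
#' @export
build_facing_table <- function(nurse_periods, patient_periods, bins,
                               nurse_ids = NULL, type_labels = NULL) {
  if (is.null(nurse_ids)) nurse_ids <- sort(unique(nurse_periods$tagID))
  if (nrow(nurse_periods) > 0 && any(nurse_periods$tagRole != "nurse")) {
    stop("input error: nurse_periods must contain only nurse rows")
  }
  ptype <- if (nrow(patient_periods) > 0) patient_type_of(patient_periods$tagRole) else character(0)
  if (is.null(type_labels)) type_labels <- sort(unique(ptype))
  ni <- match(nurse_periods$tagID, nurse_ids)
  if (anyNA(ni)) stop("input error: unknown nurse tag ", nurse_periods$tagID[which(is.na(ni))[1]])
  ti <- match(ptype, type_labels)
  if (anyNA(ti)) stop("input error: unknown patient type ", ptype[which(is.na(ti))[1]])
  nb <- bins$n_bins
  m <- length(type_labels) * nb
  counts <- matrix(0L, nrow = length(nurse_ids), ncol = m)
  if (nrow(nurse_periods) > 0 && nrow(patient_periods) > 0) {
    # pair up within zones only; cross-zone pairs can never count
    for (z in intersect(unique(nurse_periods$zID), unique(patient_periods$zID))) {
      jn <- which(nurse_periods$zID == z)
      jp <- which(patient_periods$zID == z)
      pj <- rep(jp, times = length(jn))
      nj <- rep(jn, each = length(jp))
      ov <- period_overlap(nurse_periods$st[nj], nurse_periods$et[nj],
                           patient_periods$st[pj], patient_periods$et[pj])
      keep <- ov > 0
      if (!any(keep)) next
      b <- overlap_bin(ov[keep], bins)
      col <- (ti[pj[keep]] - 1L) * nb + b
      row <- ni[nj[keep]]
      tab <- table(factor(row, levels = seq_along(nurse_ids)),
                   factor(col, levels = seq_len(m)))
      counts <- counts + matrix(as.integer(tab), nrow = length(nurse_ids))
    }
  }
  rownames(counts) <- nurse_ids
  colnames(counts) <- paste(rep(type_labels, each = nb), rep(bins$labels, length(type_labels)),
                            sep = "_")
  structure(
    list(counts = counts, nurse_ids = nurse_ids, type_labels = type_labels, bins = bins),
    class = "facing_table"
  )
}

#' @export
print.facing_table <- function(x, ...) {
  cat("<facing_table>", nrow(x$counts), "nurses x", ncol(x$counts),
      "cells (", length(x$type_labels), "types x", x$bins$n_bins, "bins );",
      "total interactions:", sum(x$counts), "\n")
  invisible(x)
}

#' @export
as.matrix.facing_table <- function(x, ...) x$counts
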