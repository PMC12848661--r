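#' @importFrom stats rexp rgamma quantile pnorm qnorm ave
#' @importFrom utils read.csv write.csv head tail
NULL

## State codes used internally: 0 = at home (initial), 1 = in hospital,
## 2 = dead (absorbing). Censoring is a status flag, never a state.
.STATES <- c(home = 0L, hospital = 1L, death = 2L)
.ALLOWED <- matrix(c(0L, 1L,
                     0L, 2L,
                     1L, 0L,
                     1L, 2L), ncol = 2, byrow = TRUE)

#' Validate and assemble an event history
#'
#' Builds a validated multistate event history from counting-process records.
#' Each record describes one sojourn of one subject: the subject occupies
#' `from` on the half-open interval `(start, stop]` and at `stop` either
#' moves to `to` (`status = 1`) or is right-censored (`status = 0`). Time
#' zero is randomization; times are in days.
#'
#' The checks enforce the structure of an illness-death process with
#' recovery: records of a subject are contiguous (each record starts where
#' and when the previous one ended), each subject starts at home at time 0,
#' every observed transition is one of home->hospital, home->death,
#' hospital->home, hospital->death, at most one absorbing (death) event per
#' subject occurs and nothing follows death or censoring, and all sojourns
#' have positive length. Ties across subjects are allowed; zero-length
#' sojourns within a subject are not.
#'
#' @param records Data frame with columns `id`, `from`, `to`, `start`,
#'   `stop`, `status` and at least the treatment covariate `Z`. `from`/`to`
#'   may use numeric codes (0 home, 1 hospital, 2 death) or progressive
#'   labels (`"R1"`, `"H1"`, `"R2"`, ..., `"D"`); censored records may carry
#'   `to = "cens"` or `NA`.
#' @param structure `"idm"` (illness-death with recovery) or
#'   `"progressive"` (states indexed by the cumulative event count). The two
#'   are projections of one record set; the tag records which view the data
#'   were generated or labelled under.
#' @return The records, sorted by subject and interval start, as an object
#'   of class `event_history` (a data frame with a `structure` attribute).
#' @export
validate_history <- function(records, structure = c("idm", "progressive")) {
  structure <- match.arg(structure)
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    out <- data.frame(id = integer(), from = integer(), to = integer(),
                      start = numeric(), stop = numeric(), status = integer(),
                      Z = numeric())
    return(new_event_history(out, structure))
  }
  records <- as.data.frame(records)
  needed <- c("id", "from", "to", "start", "stop", "status")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  records$from <- decode_state(records$from)
  records$to <- decode_state(records$to)
  records$status <- as.integer(records$status)

  if (any(is.na(records$from))) stop("unknown `from` state label")
  if (any(records$status == 0L & !is.na(records$to))) {
    stop("censored records (`status = 0`) must have the censoring marker as `to`")
  }
  if (any(records$status == 1L & is.na(records$to))) {
    stop("observed transitions (`status = 1`) must have a `to` state")
  }
  if (any(!(records$status %in% c(0L, 1L)))) stop("`status` must be 0 or 1")
  if (any(records$start < 0)) stop("`start` must be >= 0")
  if (any(records$start >= records$stop)) {
    stop("every record must have `start` < `stop` (zero-length sojourns are rejected)")
  }
  ok <- is.na(records$to) |
    apply(records[, c("from", "to")], 1L, function(r) {
      any(.ALLOWED[, 1] == r[1] & .ALLOWED[, 2] == r[2])
    })
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("transition %d->%d (row %d) is not in the allowed set",
                 records$from[bad], records$to[bad], bad))
  }

  records <- records[order(records$id, records$start), , drop = FALSE]
  rownames(records) <- NULL
  for (rows in split(seq_len(nrow(records)), records$id)) {
    r <- records[rows, ]
    if (r$from[1L] != 0L || r$start[1L] != 0) {
      stop("subject ", r$id[1L], ": history must start at home (state 0) at time 0")
    }
    n <- nrow(r)
    if (n > 1L) {
      if (any(r$start[-1L] != r$stop[-n]) || any(r$from[-1L] != r$to[-n])) {
        stop("subject ", r$id[1L],
             ": records are not contiguous (gap or state mismatch)")
      }
    }
    terminal <- which(r$status == 0L | (r$status == 1L & r$to == 2L))
    if (length(terminal) == 0L) {
      stop("subject ", r$id[1L],
           ": history must end in death or censoring")
    }
    if (min(terminal) != n) {
      stop("subject ", r$id[1L],
           ": records found after an absorbing event or censoring")
    }
  }
  new_event_history(records, structure)
}

new_event_history <- function(df, structure) {
  class(df) <- c("event_history", "data.frame")
  attr(df, "structure") <- structure
  df
}

## Accept integer codes, "cens", or progressive labels R1/H1/.../D.
decode_state <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0", "1", "2")] <- as.integer(x[x %in% c("0", "1", "2")])
  out[x == "D"] <- 2L
  out[grepl("^R[0-9]+$", x)] <- 0L
  out[grepl("^H[0-9]+$", x)] <- 1L
  out[x %in% c("cens", "NA", "")] <- NA_integer_
  out
}

#' Build a subject's records from an event list
#'
#' Converts per-subject hospitalization admission/discharge times plus a
#' terminal time (death or censoring) into counting-process records. An open
#' hospital stay at the terminal time yields a final record leaving state 1.
#'
#' @param id Subject identifier.
#' @param admissions,discharges Strictly increasing, alternating times of
#'   hospital admission and discharge (`discharges` may be one shorter when
#'   the last stay is open at the terminal time).
#' @param terminal Time of death or censoring; must be at or after the last
#'   listed event time (strictly after the last state entry).
#' @param died `TRUE` for death at `terminal`, `FALSE` for censoring.
#' @param covariates Named list of subject-level covariates (at least `Z`).
#' @return Data frame of records for this subject (not yet validated; pass
#'   through [validate_history()] to assemble a dataset).
#' @examples
#' from_event_list(1, admissions = 10, discharges = 15, terminal = 40,
#'                 died = TRUE, covariates = list(Z = 1))
#' @export
from_event_list <- function(id, admissions = numeric(), discharges = numeric(),
                            terminal, died, covariates = list(Z = 0)) {
  admissions <- as.numeric(admissions)
  discharges <- as.numeric(discharges)
  na <- length(admissions)
  nd <- length(discharges)
  if (nd > na || na - nd > 1L) {
    stop("admissions and discharges must alternate (one open stay at most)")
  }
  ev <- c(rbind(c(admissions, NA)[seq_len(max(na, nd))],
                c(discharges, NA)[seq_len(max(na, nd))]))
  ev <- ev[!is.na(ev)]
  if (length(ev) && any(diff(ev) <= 0)) {
    stop("admission/discharge times must be strictly increasing and alternating")
  }
  if (length(ev) && terminal <= max(ev)) {
    stop("terminal time must be after the last admission/discharge")
  }
  bounds <- c(0, ev, terminal)
  from <- rep(c(0L, 1L), length.out = length(bounds) - 1L)
  to <- c(from[-1L], if (died) 2L else NA_integer_)
  status <- c(rep(1L, length(from) - 1L), if (died) 1L else 0L)
  out <- data.frame(id = id, from = from, to = to,
                    start = bounds[-length(bounds)], stop = bounds[-1L],
                    status = status)
  for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  out
}

#' Risk-set size in a state just prior to a time point
#'
#' Uses the predictable (left-limit) convention: a subject transitioning out
#' of state `h` at time `t` is still at risk in `h` at `t`. For the
#' absorbing death state the occupancy counts subjects whose death occurred
#' strictly before `t` (occupancy runs from the death time onward).
#'
#' @param history An `event_history`.
#' @param state State code 0, 1, or 2.
#' @param t Time point (scalar).
#' @return Number of subjects occupying `state` just prior to `t`.
#' @export
risk_set_size <- function(history, state, t) {
  stopifnot(length(t) == 1L)
  if (!state %in% 0:2) stop("unknown state label: ", state)
  if (state == 2L) {
    return(sum(history$status == 1L & history$to == 2L & history$stop < t))
  }
  sum(history$from == state & history$start < t & history$stop >= t)
}

#' Number of completed hospitalizations strictly before a time point
#'
#' Counts completed hospital stays (discharges observed) before `t` for one
#' subject; this is the "previous hospitalizations" covariate used to probe
#' the Markov assumption. The subject must be alive and under observation at
#' `t`.
#'
#' @param history An `event_history`.
#' @param subject Subject id.
#' @param t Time point (scalar).
#' @return Integer count.
#' @export
count_previous_events <- function(history, subject, t) {
  r <- history[history$id == subject, , drop = FALSE]
  check_under_observation(r, subject, t)
  sum(r$status == 1L & r$from == 1L & r$to == 0L & r$stop < t)
}

#' Entry time into the state occupied at a time point
#'
#' @inheritParams count_previous_events
#' @return Start time (days) of the sojourn covering `t`.
#' @export
entry_time <- function(history, subject, t) {
  r <- history[history$id == subject, , drop = FALSE]
  check_under_observation(r, subject, t)
  r$start[r$start < t & r$stop >= t][1L]
}

check_under_observation <- function(r, subject, t) {
  if (nrow(r) == 0L) stop("unknown subject: ", subject)
  last <- r[nrow(r), ]
  if (last$stop < t || (last$stop == t && (last$status == 0L || last$to == 2L))) {
    stop("subject ", subject, " is already absorbed or censored at t = ", t)
  }
  invisible(NULL)
}

#' Recurrent-event count of a subject
#'
#' Right-continuous counting process of completed home->hospital transitions
#' in `[0, t]`.
#'
#' @inheritParams count_previous_events
#' @return Integer count of hospital admissions by `t`.
#' @export
n_recurrent <- function(history, subject, t) {
  r <- history[history$id == subject, , drop = FALSE]
  if (nrow(r) == 0L) stop("unknown subject: ", subject)
  sum(r$status == 1L & r$from == 0L & r$to == 1L & r$stop <= t)
}

#' Write an event history as delimited text
#'
#' Long-format CSV with header `id,from,to,start,stop,status,Z[,...]`, one
#' row per record, rows ordered by subject and interval start. Censored
#' records carry the marker `"cens"` in the `to` column. With
#' `labels = "progressive"` the states are written as `R1,H1,R2,...,D`
#' (at home after k-1 hospitalizations, k-th hospital stay, death); the two
#' labelings are projections of the same record set.
#'
#' @param history An `event_history`.
#' @param path Output file path.
#' @param labels `"idm"` for numeric codes or `"progressive"`.
#' @export
write_event_history <- function(history, path, labels = c("idm", "progressive")) {
  labels <- match.arg(labels)
  df <- as.data.frame(history)
  df <- df[order(df$id, df$start), , drop = FALSE]
  if (labels == "idm") {
    df$to <- ifelse(df$status == 0L, "cens", as.character(df$to))
  } else {
    prev <- prev_admissions(df)
    lab <- function(state, k) {
      ifelse(state == 2L, "D", ifelse(state == 0L, paste0("R", k + 1L),
                                      paste0("H", k)))
    }
    ## entering hospital increments the admission count
    df$to <- ifelse(df$status == 0L, "cens",
                    lab(df$to, prev + (df$from == 0L & df$to == 1L)))
    df$from <- lab(df$from, prev)
  }
  ## full double precision so that written times round-trip bit-exactly
  df$start <- sprintf("%.17g", df$start)
  df$stop <- sprintf("%.17g", df$stop)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event history written by [write_event_history()]
#'
#' Accepts both numeric illness-death codes and progressive labels.
#'
#' @param path CSV file path.
#' @param structure Structure tag passed to [validate_history()].
#' @return An `event_history`.
#' @export
read_event_history <- function(path, structure = c("idm", "progressive")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_history(df, match.arg(structure))
}

## number of hospital admissions of the subject strictly before each
## record's start (vectorized over a record data frame sorted by id, start)
prev_admissions <- function(df) {
  adm <- as.integer(df$status == 1L & df$from == 0L & df$to == 1L)
  ave(adm, df$id, FUN = function(v) cumsum(c(0L, head(v, -1L))))
}

#' Per-dataset summaries of an event history
#'
#' @param history An `event_history`.
#' @return List with the number of subjects, number censored, number dead,
#'   total number of hospital admissions, and the maximum per-subject number
#'   of (re)hospitalizations.
#' @export
dataset_summary <- function(history) {
  ids <- unique(history$id)
  adm <- history$status == 1L & history$from == 0L & history$to == 1L
  per <- table(factor(history$id[adm], levels = ids))
  list(n = length(ids),
       n_censored = sum(history$status == 0L),
       n_dead = sum(history$status == 1L & history$to == 2L),
       n_admissions = sum(adm),
       max_rehosp = if (length(per)) max(per) else 0L)
}
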