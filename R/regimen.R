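#' Drug administration regimen
#'
#' Day-indexed schedules for the xenograft experiments. Codes: `AO`/`GO`/
#' `OA`/`OG` = sequential therapy switched on `switch_day`; `A+O`, `G+O` =
#' simultaneous combinations; `AO3` = 3-day alternation of afatinib and
#' osimertinib; `A`, `O`, `G` = monotherapies; `vehicle` = no drug.
#' Treatment runs from `start_day` (tumors are engrafted on day 0) to
#' `duration`.
#'
#' @param name Regimen code.
#' @param start_day First treatment day (default 6).
#' @param switch_day Day the sequential regimens switch drugs (default 16).
#' @param duration Last day of the experiment (default 30).
#' @param alternation_days Block length for `AO3` (default 3).
#' @return A `regimen` object: list with `name`, `schedule` (data.frame
#'   `from`, `to`, `drugs`; contiguous, non-overlapping intervals covering
#'   \[0, duration\]), `start_day`, `switch_day`, `duration`.
#' @export
regimen <- function(name = c("AO", "GO", "OA", "OG", "A+O", "G+O", "AO3",
                             "A", "O", "G", "vehicle"),
                    start_day = 6, switch_day = 16, duration = 30,
                    alternation_days = 3) {
  name <- match.arg(name)
  stopifnot(start_day >= 0, duration > start_day)
  drug1 <- c(A = "afatinib", G = "gefitinib", O = "osimertinib")
  seg <- function(from, to, drugs) data.frame(from = from, to = to,
                                              drugs = I(list(drugs)))
  pre <- seg(0, start_day, character())
  sched <- switch(
    name,
    vehicle = seg(start_day, duration, character()),
    A = seg(start_day, duration, "afatinib"),
    O = seg(start_day, duration, "osimertinib"),
    G = seg(start_day, duration, "gefitinib"),
    "A+O" = seg(start_day, duration, c("afatinib", "osimertinib")),
    "G+O" = seg(start_day, duration, c("gefitinib", "osimertinib")),
    AO3 = {
      starts <- seq(start_day, duration - 1e-9, by = alternation_days)
      ends <- pmin(starts + alternation_days, duration)
      do.call(rbind, lapply(seq_along(starts), function(i)
        seg(starts[i], ends[i],
            if (i %% 2 == 1) "afatinib" else "osimertinib")))
    },
    {
      if (switch_day <= start_day || switch_day >= duration)
        stop("switch_day must lie inside (start_day, duration)")
      first <- unname(drug1[substr(name, 1, 1)])
      second <- unname(drug1[substr(name, 2, 2)])
      rbind(seg(start_day, switch_day, first),
            seg(switch_day, duration, second))
    })
  sched <- rbind(pre, sched)
  structure(list(name = name, schedule = sched, start_day = start_day,
                 switch_day = switch_day, duration = duration),
            class = "regimen")
}

#' @export
print.regimen <- function(x, ...) {
  cat("regimen", x$name, "\n")
  for (i in seq_len(nrow(x$schedule))) {
    d <- x$schedule$drugs[[i]]
    cat(sprintf("  day %4.1f-%4.1f: %s\n", x$schedule$from[i],
                x$schedule$to[i],
                if (length(d)) paste(d, collapse = " + ") else "none"))
  }
  invisible(x)
}

#' Drugs administered on a given day
#'
#' @param x A [regimen()].
#' @param day Day (fractional allowed).
#' @return Character vector of drug names active at that day (possibly
#'   empty).
#' @export
drugs_at_day <- function(x, day) {
  stopifnot(inherits(x, "regimen"))
  if (day < 0 || day > x$duration)
    stop("day outside the regimen's covered interval [0, ", x$duration, "]")
  i <- which(day >= x$schedule$from & day < x$schedule$to)
  if (!length(i)) i <- nrow(x$schedule)  # day == duration
  x$schedule$drugs[[i[1]]]
}
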