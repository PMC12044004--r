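#' Demographic model for the structured coalescent
#'
#' Describes a set of populations with present-day diploid effective sizes and
#' a time-ordered list of backwards-in-time events: population splits (the
#' derived population's lineages merge into the ancestral one), instantaneous
#' size changes, and bottlenecks (a reduced size over a time interval).
#' Time is measured in generations before present; sizes are diploid N.
#'
#' @param pop_names ordered character vector of population names.
#' @param pop_sizes present-day diploid effective sizes, one per population.
#' @param events list of events built with [event_split()],
#'   [event_size_change()], [event_bottleneck()].
#' @param mu mutation rate per bp per generation.
#' @param gen_time_years generation time in years (annual plants: 1).
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(pop_names, pop_sizes, events = list(),
                              mu = 6.5e-9, gen_time_years = 1) {
  pop_names <- as.character(pop_names)
  if (anyDuplicated(pop_names)) stop("population names must be unique")
  if (length(pop_sizes) != length(pop_names))
    stop("one size per population required")
  if (any(pop_sizes <= 0)) stop("population sizes must be positive")
  if (mu <= 0) stop("mutation rate must be positive")
  m <- structure(list(pop_names = pop_names,
                      pop_sizes = as.numeric(pop_sizes),
                      events = events, mu = mu,
                      gen_time_years = gen_time_years),
                 class = "demographic_model")
  validate_model(m)
  m
}

#' Demographic events
#'
#' @param time event time in generations before present.
#' @param derived,ancestral,pop population names.
#' @param size diploid effective size.
#' @param start,end bottleneck interval in generations before present
#'   (`start` is the more recent edge).
#' @return an event list element.
#' @name demographic_events
NULL

#' @rdname demographic_events
#' @export
event_split <- function(time, derived, ancestral) {
  if (time < 0) stop("event times must be >= 0")
  list(type = "split", time = time, derived = derived, ancestral = ancestral)
}

#' @rdname demographic_events
#' @export
event_size_change <- function(time, pop, size) {
  if (time < 0) stop("event times must be >= 0")
  if (size <= 0) stop("sizes must be positive")
  list(type = "size_change", time = time, pop = pop, size = size)
}

#' @rdname demographic_events
#' @export
event_bottleneck <- function(start, end, pop, size) {
  if (start < 0 || end <= start) stop("bottleneck requires 0 <= start < end")
  if (size <= 0) stop("sizes must be positive")
  list(type = "bottleneck", time = start, end = end, pop = pop, size = size)
}

validate_model <- function(m) {
  pops <- m$pop_names
  split_from <- character(0)
  for (e in m$events) {
    nm <- switch(e$type, split = c(e$derived, e$ancestral),
                 size_change = e$pop, bottleneck = e$pop,
                 stop("unknown event type: ", e$type))
    if (!all(nm %in% pops)) stop("event references unknown population")
    if (e$type == "split") {
      if (e$derived %in% split_from)
        stop("population ", e$derived, " splits more than once")
      split_from <- c(split_from, e$derived)
    }
  }
  # every population except one must eventually merge into the tree
  if (length(pops) > 1 && length(split_from) < length(pops) - 1)
    stop("splits must merge all populations into a single ancestor")
  invisible(TRUE)
}

# compile events into the flat arrays the C++ engine consumes; bottlenecks
# become a resize at `start` and a restore at `end` (to the size the ordinary
# size-change timeline implies at that time)
compile_model <- function(m) {
  pops <- m$pop_names
  pidx <- function(p) match(p, pops) - 1L
  size_at <- function(pop, t) {
    sz <- m$pop_sizes[match(pop, pops)]
    evs <- Filter(function(e) e$type == "size_change" && e$pop == pop &&
                    e$time <= t, m$events)
    if (length(evs)) {
      times <- vapply(evs, `[[`, numeric(1), "time")
      sz <- evs[[which.max(times)]]$size
    }
    sz
  }
  rows <- list()
  for (e in m$events) {
    if (e$type == "split") {
      rows[[length(rows) + 1]] <- list(time = e$time, type = 0L,
                                       p1 = pidx(e$derived),
                                       p2 = pidx(e$ancestral), size = 0)
    } else if (e$type == "size_change") {
      rows[[length(rows) + 1]] <- list(time = e$time, type = 1L,
                                       p1 = pidx(e$pop), p2 = -1L,
                                       size = e$size)
    } else { # bottleneck
      rows[[length(rows) + 1]] <- list(time = e$time, type = 1L,
                                       p1 = pidx(e$pop), p2 = -1L,
                                       size = e$size)
      rows[[length(rows) + 1]] <- list(time = e$end, type = 1L,
                                       p1 = pidx(e$pop), p2 = -1L,
                                       size = size_at(e$pop, e$end))
    }
  }
  if (!length(rows)) {
    return(list(ev_time = numeric(0), ev_type = integer(0),
                ev_p1 = integer(0), ev_p2 = integer(0), ev_size = numeric(0)))
  }
  tm <- vapply(rows, `[[`, numeric(1), "time")
  o <- order(tm)
  list(ev_time = tm[o],
       ev_type = vapply(rows, `[[`, integer(1), "type")[o],
       ev_p1 = vapply(rows, function(r) as.integer(r$p1), integer(1))[o],
       ev_p2 = vapply(rows, function(r) as.integer(r$p2), integer(1))[o],
       ev_size = vapply(rows, `[[`, numeric(1), "size")[o])
}

#' Two-pair domestication demography
#'
#' Convenience constructor for the study design: two cultivated/wild pairs
#' (`exilis`/`longiflora` and `iburua`/`ternata` by default), a deep split
#' between the pairs, recent within-pair splits, and an optional
#' post-divergence bottleneck followed by expansion in each cultivated
#' lineage.
#'
#' @param pop_names four population names, ordered
#'   (cultivated1, wild1, cultivated2, wild2).
#' @param sizes named or ordered diploid sizes for the four populations.
#' @param t_split1,t_split2 within-pair divergence times (generations).
#' @param t_deep between-pair divergence time (generations).
#' @param bottleneck_sizes reduced diploid sizes of the two cultivated
#'   lineages during their post-divergence bottlenecks (`NULL` for none).
#' @param bottleneck_ends generations at which each bottleneck ends
#'   (recent edge; the bottleneck runs from there back to the pair's split).
#' @param n_anc ancestral diploid size (applied to the wild lineages above
#'   the within-pair splits and to the root).
#' @param mu,gen_time_years passed to [demographic_model()].
#' @return a `demographic_model` over the four populations.
#' @export
two_pair_model <- function(pop_names = c("exilis", "longiflora", "iburua", "ternata"),
                           sizes = c(1e4, 1e4, 1e4, 1e4),
                           t_split1 = 25000, t_split2 = 10000,
                           t_deep = 150000,
                           bottleneck_sizes = NULL,
                           bottleneck_ends = c(2000, 3000),
                           n_anc = 1e4,
                           mu = 6.5e-9, gen_time_years = 1) {
  stopifnot(length(pop_names) == 4, t_deep > max(t_split1, t_split2))
  c1 <- pop_names[1]; w1 <- pop_names[2]; c2 <- pop_names[3]; w2 <- pop_names[4]
  ev <- list(
    event_split(t_split1, c1, w1),
    event_split(t_split2, c2, w2),
    event_size_change(t_split1, w1, n_anc),
    event_size_change(t_split2, w2, n_anc),
    event_split(t_deep, w2, w1)
  )
  if (!is.null(bottleneck_sizes)) {
    ev <- c(ev, list(
      event_bottleneck(bottleneck_ends[1], t_split1, c1, bottleneck_sizes[1]),
      event_bottleneck(bottleneck_ends[2], t_split2, c2, bottleneck_sizes[2])
    ))
  }
  demographic_model(pop_names, sizes, ev, mu = mu,
                    gen_time_years = gen_time_years)
}
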