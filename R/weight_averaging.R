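# Phase 3: "model soup" uniform weight averaging.
#
# Self-distilled students differ only through the random seed of their
# (discarded) projection heads; averaging their parameters elementwise
# yields a single model at no inference cost.

#' Parameter snapshot of an encoder
#'
#' Extracts the named parameter arrays and architecture tag of an encoder
#' into a plain snapshot suitable for [soup_average()]. Parameter names are
#' enumerated in a stable (sorted) order.
#'
#' @param enc A `lord_encoder`.
#' @return Object of class `param_snapshot` with `architecture_tag` and
#'   `params` (named list of arrays).
#' @export
encoder_snapshot <- function(enc) {
  stopifnot(inherits(enc, "lord_encoder"))
  params <- enc$params[order(names(enc$params), method = "radix")]
  structure(list(architecture_tag = enc$arch, params = params),
            class = "param_snapshot")
}

as_snapshot <- function(x) {
  if (inherits(x, "param_snapshot")) return(x)
  if (inherits(x, "lord_encoder")) return(encoder_snapshot(x))
  stop_input("cannot snapshot an object of class %s", class(x)[[1L]])
}

#' Uniform model soup
#'
#' Elementwise uniform mean of the parameter arrays of several snapshots
#' (or encoders) sharing one architecture. Arrays whose name matches
#' `exclude` — by default anything under a `head.` prefix — are dropped
#' rather than averaged: projection heads are seed-specific and discarded.
#' When encoders are passed, an encoder with the averaged parameters is
#' returned (a copy of the first input); otherwise a `param_snapshot`.
#'
#' @param snapshots Non-empty list of `param_snapshot`s or `lord_encoder`s.
#' @param exclude Regular expression for parameter names excluded from the
#'   soup.
#' @return Averaged encoder or snapshot, matching the input type.
#' @examples
#' a <- make_reference_encoder(4, 16, seed = 1)
#' b <- make_reference_encoder(4, 16, seed = 2)
#' soup <- soup_average(list(a, b))
#' @export
soup_average <- function(snapshots, exclude = "^head\\.") {
  if (!is.list(snapshots) || length(snapshots) < 1L) {
    stop_input("`snapshots` must be a non-empty list")
  }
  return_encoder <- inherits(snapshots[[1L]], "lord_encoder")
  snaps <- lapply(snapshots, as_snapshot)
  tag <- snaps[[1L]]$architecture_tag
  keep <- grep(exclude, names(snaps[[1L]]$params), value = TRUE,
               invert = TRUE)
  ref <- snaps[[1L]]$params[keep]
  for (s in snaps[-1L]) {
    if (!identical(s$architecture_tag, tag)) {
      stop_input("architecture tag mismatch: '%s' vs '%s'",
                 s$architecture_tag, tag)
    }
    other <- grep(exclude, names(s$params), value = TRUE, invert = TRUE)
    if (!identical(sort(other), sort(keep))) {
      stop_input("parameter name mismatch on array '%s'",
                 setdiff(union(other, keep), intersect(other, keep))[[1L]])
    }
    for (nm in keep) {
      if (!identical(dim_or_len(s$params[[nm]]), dim_or_len(ref[[nm]]))) {
        stop_input("shape mismatch on array '%s'", nm)
      }
    }
  }
  avg <- ref
  for (nm in keep) {
    acc <- snaps[[1L]]$params[[nm]]
    for (s in snaps[-1L]) acc <- acc + s$params[[nm]]
    avg[[nm]] <- acc / length(snaps)
  }
  if (return_encoder) {
    out <- snapshots[[1L]]
    out$params[keep] <- avg[keep]
    attr(out, "history") <- NULL
    out
  } else {
    structure(list(architecture_tag = tag, params = avg),
              class = "param_snapshot")
  }
}

dim_or_len <- function(a) dim(a) %||% length(a)
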