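#' Define a reference community
#'
#' A reference community is the ground truth against which observed taxa are
#' benchmarked: a set of member 16S sequences, optionally with the expected
#' relative-abundance profile (as for commercial mock standards, which come
#' either evenly distributed or as a log-distributed dilution series).
#'
#' @param members named character vector of reference DNA sequences.
#' @param expected_profile optional named numeric vector of expected
#'   relative abundances over the members; must sum to 1.
#' @param distribution_label one of `"even"`, `"log"`, `"custom"`.
#' @return an object of class `reference_community`.
#' @export
reference_community <- function(members, expected_profile = NULL,
                                distribution_label = c("custom", "even", "log")) {
  distribution_label <- match.arg(distribution_label)
  validate_sequence_set(members)
  if (!is.null(expected_profile)) {
    if (is.null(names(expected_profile)) ||
        !setequal(names(expected_profile), names(members))) {
      stop("expected_profile must be named by the member ids")
    }
    expected_profile <- expected_profile[names(members)]
    if (abs(sum(expected_profile) - 1) > 1e-9) {
      stop("expected_profile must sum to 1")
    }
    if (any(expected_profile < 0)) stop("expected_profile must be non-negative")
  }
  structure(list(members = members, expected_profile = expected_profile,
                 distribution_label = distribution_label),
            class = "reference_community")
}

#' @export
print.reference_community <- function(x, ...) {
  cat("<reference_community>", length(x$members), "members,",
      x$distribution_label, "profile\n")
  invisible(x)
}

# accept either a reference_community or a bare named sequence vector
reference_members <- function(ref) {
  members <- if (inherits(ref, "reference_community")) ref$members else ref
  if (length(members) == 0L) stop("empty reference set")
  validate_sequence_set(members)
  members
}

#' Member ids of a reference community
#'
#' @param ref a [reference_community()] or named sequence vector.
#' @return character vector of member ids.
#' @export
reference_ids <- function(ref) {
  names(reference_members(ref))
}
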