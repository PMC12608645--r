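#' Load the metabolic network parameter table
#'
#' The kinetic and regulatory parameters of the 53-variable gene-metabolism
#' network ship as an editable CSV (columns: reaction, name, value, units,
#' note). Parameter names must exactly cover the set the network kernel
#' expects: missing or unknown names fail fast.
#'
#' @param file Path to a parameter CSV. Default: the table shipped with the
#'   package.
#' @return A named numeric vector of parameters (class `msx_params`).
#' @export
metabolic_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "metabolic_parameters.csv",
                        package = "metaspheroid")
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "value") %in% names(tab)))
  if (anyDuplicated(tab$name)) {
    stop("duplicated parameter names in ", file)
  }
  p <- stats::setNames(as.numeric(tab$value), tab$name)
  expected <- msx_param_names()
  missing <- setdiff(expected, names(p))
  extra <- setdiff(names(p), expected)
  if (length(missing)) {
    stop("parameter table is missing: ", paste(missing, collapse = ", "))
  }
  if (length(extra)) {
    stop("parameter table has unknown entries: ", paste(extra, collapse = ", "))
  }
  p <- p[expected]
  class(p) <- c("msx_params", "numeric")
  p
}

#' Names of the 53 state variables of the metabolic network
#'
#' @return Character vector of length 53 (metabolites, then the ten gene
#'   expressions, then their protein products).
#' @export
metabolic_state_names <- function() {
  msx_state_names()
}

#' Basal metabolic state
#'
#' Returns the basal (well-fed, normoxic) steady state of the network, as
#' shipped in `inst/extdata/basal_state.csv`. This is the reference initial
#' condition for every cell at simulation start.
#'
#' @return Named numeric vector of length 53.
#' @keywords internal
basal_state_table <- function() {
  file <- system.file("extdata", "basal_state.csv", package = "metaspheroid")
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  s <- stats::setNames(as.numeric(tab$value), tab$variable)
  expected <- msx_state_names()
  if (!identical(names(s), expected)) {
    stop("basal state table does not match the network state layout")
  }
  s
}

#' Initialize a per-cell metabolic state
#'
#' Starts a cell at the basal steady-state values of the network. The
#' gamma parameter (per-cell gene-regulation modulation) is stored as an
#' attribute; `rng_seed` is kept for interface symmetry - initialization
#' itself is deterministic.
#'
#' @param gamma Positive gene-regulation modulation factor.
#' @param rng_seed Integer seed recorded with the state.
#' @return Named numeric vector of length 53 (class `msx_state`) with
#'   attributes `gamma` and `rng_seed`.
#' @export
init_state <- function(gamma = 1, rng_seed = 0L) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  s <- basal_state_table()
  if (any(s < 0)) stop("basal state contains negative entries")
  attr(s, "gamma") <- gamma
  attr(s, "rng_seed") <- rng_seed
  class(s) <- c("msx_state", "numeric")
  s
}
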