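#' The 16-state metastasis seeding network
#'
#' Metastatic involvement of bone, lung, liver and brain is encoded as four
#' binary flags; each of the \eqn{2^4 = 16} combinations is a state of a
#' continuous-time Markov chain. State 1 is metastasis-free, state 16 has all
#' four sites involved. A transition adds exactly one site (metastases do not
#' regress), so state 16 is absorbing. Six dissemination rates drive the
#' chain: four primary routes from the tumor (\code{tubo}, \code{tulu},
#' \code{tuli}, \code{tubr} to bone/lung/liver/brain) and two secondary routes
#' from an established lung metastasis (\code{luli} to liver, \code{lubr} to
#' brain), all per year.
#'
#' @section State indexing:
#' The index-to-flag mapping is the one fixed by the published transition
#' diagram: states 2--5 are the single-site states liver, brain, lung, bone in
#' that order; state 7 is bone+brain ("1001" in bone/lung/liver/brain bit
#' order); state 16 is all four. `met_states()` returns the full table.
#'
#' @name state_network
NULL

# index -> (bone, lung, liver, brain); reconstructed from the transition list
# of the state diagram (unique solution; re-derived by constraint propagation
# in the test suite).
.STATE_FLAGS <- matrix(c(
  0, 0, 0, 0, # 1
  0, 0, 1, 0, # 2  liver
  0, 0, 0, 1, # 3  brain
  0, 1, 0, 0, # 4  lung
  1, 0, 0, 0, # 5  bone
  0, 1, 1, 0, # 6  lung+liver
  1, 0, 0, 1, # 7  bone+brain
  1, 1, 0, 0, # 8  bone+lung
  0, 1, 0, 1, # 9  lung+brain
  1, 0, 1, 0, # 10 bone+liver
  0, 0, 1, 1, # 11 liver+brain
  1, 0, 1, 1, # 12 bone+liver+brain
  1, 1, 1, 0, # 13 bone+lung+liver
  1, 1, 0, 1, # 14 bone+lung+brain
  0, 1, 1, 1, # 15 lung+liver+brain
  1, 1, 1, 1  # 16 all
), ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("bone", "lung", "liver", "brain")))

.SITES <- c("bone", "lung", "liver", "brain")
.RATE_NAMES <- c("tubo", "tulu", "tuli", "tubr", "luli", "lubr")

#' Enumerate the 16 metastasis states
#'
#' @return A data frame with columns \code{index} (1--16), the four site flags
#'   \code{bone}, \code{lung}, \code{liver}, \code{brain} (0/1), and
#'   \code{label}, the flags concatenated in bone/lung/liver/brain order
#'   (state 7 is \code{"1001"}).
#' @examples
#' met_states()
#' @export
met_states <- function() {
  data.frame(
    index = 1:16,
    .STATE_FLAGS,
    label = apply(.STATE_FLAGS, 1L, paste, collapse = "")
  )
}

#' Map site flags to a state index
#'
#' @param bone,lung,liver,brain 0/1 flags (vectorized).
#' @return Integer state index (1--16).
#' @examples
#' state_index(1, 0, 0, 1) # bone + brain -> 7
#' @export
state_index <- function(bone, lung, liver, brain) {
  flags <- cbind(bone, lung, liver, brain)
  if (any(is.na(flags)) || !all(flags %in% c(0, 1)))
    stop("site flags must be 0 or 1 and non-missing")
  key <- paste(flags[, 1], flags[, 2], flags[, 3], flags[, 4])
  tab <- paste(.STATE_FLAGS[, 1], .STATE_FLAGS[, 2],
               .STATE_FLAGS[, 3], .STATE_FLAGS[, 4])
  match(key, tab)
}

#' Construct a vector of the six dissemination rates
#'
#' @param tubo,tulu,tuli,tubr Primary seeding rates tumor-to-bone/-lung/
#'   -liver/-brain, per year.
#' @param luli,lubr Secondary seeding rates lung-to-liver and lung-to-brain,
#'   per year.
#' @return A named numeric vector of class \code{rate_vector}.
#' @examples
#' rate_vector(tulu = 0.00269, luli = 0.126, lubr = 0.0404)
#' @export
rate_vector <- function(tubo = 0, tulu = 0, tuli = 0, tubr = 0,
                        luli = 0, lubr = 0) {
  theta <- c(tubo = tubo, tulu = tulu, tuli = tuli, tubr = tubr,
             luli = luli, lubr = lubr)
  validate_rates(theta)
}

#' @rdname rate_vector
#' @param theta A numeric vector with the six rate components (named or in
#'   \code{tubo, tulu, tuli, tubr, luli, lubr} order).
#' @export
as_rate_vector <- function(theta) {
  if (is.null(names(theta))) {
    stopifnot(length(theta) == 6L)
    names(theta) <- .RATE_NAMES
  }
  validate_rates(theta[.RATE_NAMES])
}

validate_rates <- function(theta) {
  if (length(theta) != 6L || !all(.RATE_NAMES %in% names(theta)))
    stop("a rate vector has the six components ",
         paste(.RATE_NAMES, collapse = ", "))
  theta <- theta[.RATE_NAMES]
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("dissemination rates must be finite and non-negative")
  class(theta) <- c("rate_vector", "numeric")
  theta
}

#' Transition rate between two states
#'
#' Nonzero only when \code{to} equals \code{from} with exactly one additional
#' positive site \code{k}. The rate is the tumor-to-\code{k} rate plus, when
#' the originating state has a lung metastasis and \code{k} is liver or brain,
#' the corresponding secondary rate (\code{luli} or \code{lubr}).
#'
#' @param from,to State indices (1--16).
#' @param theta A [rate_vector()].
#' @return Rate per year; 0 for any pair that is not a single-site addition.
#' @examples
#' th <- rate_vector(tuli = 0.0015, luli = 0.126)
#' transition_rate(4, 6, th) # lung -> lung+liver: tuli + luli
#' @export
transition_rate <- function(from, to, theta) {
  theta <- as_rate_vector(theta)
  f <- .STATE_FLAGS[from, ]
  t <- .STATE_FLAGS[to, ]
  added <- which(t == 1 & f == 0)
  if (length(added) != 1L || any(f == 1 & t == 0)) return(0)
  site <- .SITES[added]
  primary <- c(bone = theta[["tubo"]], lung = theta[["tulu"]],
               liver = theta[["tuli"]], brain = theta[["tubr"]])
  r <- primary[[site]]
  if (f[["lung"]] == 1) {
    if (site == "liver") r <- r + theta[["luli"]]
    if (site == "brain") r <- r + theta[["lubr"]]
  }
  r
}

#' Build the 16x16 rate generator
#'
#' Entry \code{Q[i, j]} is the rate of moving from state \code{j} to state
#' \code{i} (column-to-row orientation, matching the master equation
#' \eqn{dP/dt = QP}); the diagonal holds minus the total exit rate, so every
#' column sums to zero. The column of state 16 is identically zero
#' (absorbing).
#'
#' @param theta A [rate_vector()].
#' @return A 16x16 numeric matrix.
#' @examples
#' Q <- build_generator(rate_vector(tubo = 0.006, tulu = 0.0027))
#' colSums(Q) # all ~0
#' @export
build_generator <- function(theta) {
  theta <- as_rate_vector(theta)
  matrix(generator_basis() %*% theta, 16, 16)
}

# Q is linear in the six rates; cache the 256 x 6 coefficient basis built
# from the definitional transition_rate() so repeated likelihood evaluations
# avoid the double loop.
.basis_cache <- new.env(parent = emptyenv())
generator_basis <- function() {
  if (!is.null(.basis_cache$B)) return(.basis_cache$B)
  B <- matrix(0, 256, 6, dimnames = list(NULL, .RATE_NAMES))
  for (k in seq_along(.RATE_NAMES)) {
    unit <- validate_rates(stats::setNames(as.numeric(seq_len(6) == k),
                                           .RATE_NAMES))
    Q <- matrix(0, 16, 16)
    for (j in 1:16) for (i in 1:16) {
      if (i != j) Q[i, j] <- transition_rate(j, i, unit)
    }
    diag(Q) <- -colSums(Q)
    B[, k] <- as.numeric(Q)
  }
  .basis_cache$B <- B
  B
}

#' Edge list of the seeding-state network
#'
#' All 32 allowed single-site-addition transitions with their symbolic rate
#' expression and, if \code{theta} is given, the numeric rate.
#'
#' @param theta Optional [rate_vector()] to evaluate rates.
#' @return Data frame with \code{from}, \code{to}, \code{rate_expression} and
#'   (optionally) \code{rate}.
#' @export
network_edges <- function(theta = NULL) {
  ones <- rate_vector(1, 1, 1, 1, 1, 1)
  out <- list()
  for (j in 1:16) for (i in 1:16) {
    if (i == j || transition_rate(j, i, ones) == 0) next
    added <- .SITES[which(.STATE_FLAGS[i, ] == 1 & .STATE_FLAGS[j, ] == 0)]
    expr <- switch(added,
      bone = "tubo", lung = "tulu",
      liver = if (.STATE_FLAGS[j, "lung"] == 1) "tuli + luli" else "tuli",
      brain = if (.STATE_FLAGS[j, "lung"] == 1) "tubr + lubr" else "tubr")
    out[[length(out) + 1L]] <- data.frame(from = j, to = i,
                                          rate_expression = expr)
  }
  edges <- do.call(rbind, out)
  edges <- edges[order(edges$from, edges$to), ]
  rownames(edges) <- NULL
  if (!is.null(theta)) {
    theta <- as_rate_vector(theta)
    edges$rate <- mapply(transition_rate, edges$from, edges$to,
                         MoreArgs = list(theta = theta))
  }
  edges
}

#' Write the transition edge list as CSV
#'
#' @param path Output file.
#' @param theta Optional [rate_vector()]; adds a numeric \code{rate} column.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(path, theta = NULL) {
  utils::write.csv(network_edges(theta), path, row.names = FALSE)
  invisible(path)
}

#' Write the state network as a DOT graph
#'
#' @param path Output file.
#' @param theta Optional [rate_vector()]; numeric rates are added to edge
#'   labels when given.
#' @return `path`, invisibly.
#' @export
write_network_dot <- function(path, theta = NULL) {
  edges <- network_edges(theta)
  st <- met_states()
  lines <- c("digraph metastasis_states {",
             "  rankdir=LR;",
             sprintf("  s%d [label=\"%d\\n%s\"];", st$index, st$index,
                     st$label))
  lab <- edges$rate_expression
  if (!is.null(edges$rate))
    lab <- sprintf("%s = %.4g", lab, edges$rate)
  lines <- c(lines,
             sprintf("  s%d -> s%d [label=\"%s\"];", edges$from, edges$to,
                     lab),
             "}")
  writeLines(lines, path)
  invisible(path)
}
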