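test_that("state enumeration matches the published diagram and is unique", {
  st <- met_states()
  expect_equal(nrow(st), 16L)
  expect_equal(st$index, 1:16)
  # bijection
  expect_equal(anyDuplicated(st$label), 0L)
  # anchors: metastasis-free start, bone+brain as state 7, full involvement
  expect_equal(unlist(st[1, c("bone", "lung", "liver", "brain")],
                      use.names = FALSE), c(0, 0, 0, 0))
  expect_equal(st$label[7], "1001")
  expect_equal(st$label[16], "1111")
  # single-site states forced by the 1 -> 2/3/4/5 transitions
  expect_equal(st$label[2], "0010") # liver
  expect_equal(st$label[3], "0001") # brain
  expect_equal(st$label[4], "0100") # lung
  expect_equal(st$label[5], "1000") # bone
  # the mapping is re-derivable, uniquely, from the transition list alone
  derived <- derive_state_flags()
  expect_false(anyNA(derived))
  expect_equal(unname(derived),
               unname(as.matrix(st[, c("bone", "lung", "liver", "brain")])))
})

test_that("transition rates follow the single-site-addition rule", {
  th <- rate_vector(tubo = 1, tulu = 2, tuli = 3, tubr = 4,
                    luli = 10, lubr = 20)
  expect_equal(transition_rate(1, 5, th), 1)            # tumor -> bone
  expect_equal(transition_rate(4, 6, th), 3 + 10)       # tuli + luli
  expect_equal(transition_rate(4, 9, th), 4 + 20)       # tubr + lubr
  expect_equal(transition_rate(5, 10, th), 3)           # no lung: tuli only
  expect_equal(transition_rate(15, 16, th), 1)          # adds bone: tubo
  expect_equal(transition_rate(10, 13, th), 2)          # adds lung: tulu
  # no regression, no multi-site jumps, absorbing final state
  expect_equal(transition_rate(5, 4, th), 0)
  expect_equal(transition_rate(1, 6, th), 0)
  for (i in 1:15) expect_equal(transition_rate(16, i, th), 0)
})

test_that("every caption transition evaluates to its printed rate expression", {
  th <- rate_vector(tubo = 0.11, tulu = 0.23, tuli = 0.31, tubr = 0.47,
                    luli = 0.59, lubr = 0.73)
  vals <- c(tubo = 0.11, tulu = 0.23, tuli = 0.31, tubr = 0.47,
            luli = 0.59, lubr = 0.73)
  edges <- caption_edges()
  for (r in seq_len(nrow(edges))) {
    expected <- sum(vals[strsplit(edges$expr[r], "+", fixed = TRUE)[[1]]])
    expect_equal(transition_rate(edges$from[r], edges$to[r], th), expected,
                 info = paste(edges$from[r], "->", edges$to[r]))
  }
  # and these 32 are the only allowed transitions
  allowed <- network_edges()
  expect_equal(nrow(allowed), 32L)
  expect_equal(allowed[c("from", "to")],
               edges[order(edges$from, edges$to), c("from", "to")],
               ignore_attr = TRUE)
})

test_that("generator conserves probability and reproduces the state-7 balance", {
  th <- rate_vector(tubo = 0.11, tulu = 0.23, tuli = 0.31, tubr = 0.47,
                    luli = 0.59, lubr = 0.73)
  Q <- build_generator(th)
  expect_lt(max(abs(colSums(Q))), 1e-12)
  offdiag <- Q; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  expect_equal(sum(offdiag > 0), 32L)
  expect_equal(Q[, 16], rep(0, 16))                       # absorbing
  expect_equal(Q[7, 7], -(0.31 + 0.23))                   # -(tuli + tulu)
  expect_equal(Q[7, 3], 0.11)                             # tubo into 7
  expect_equal(Q[7, 5], 0.47)                             # tubr into 7
  expect_equal(Q[1, 1], -(0.11 + 0.23 + 0.31 + 0.47))
  expect_equal(build_generator(rate_vector()), matrix(0, 16, 16))
  expect_error(as_rate_vector(c(-1, 1, 1, 1, 1, 1)), "non-negative")
})

test_that("all states are reachable and transitions add exactly one site", {
  st <- as.matrix(met_states()[, c("bone", "lung", "liver", "brain")])
  edges <- network_edges()
  popcount <- rowSums(st)
  for (r in seq_len(nrow(edges)))
    expect_equal(popcount[edges$to[r]], popcount[edges$from[r]] + 1)
  # breadth-first search from the metastasis-free state
  reached <- 1L
  repeat {
    nxt <- unique(c(reached, edges$to[edges$from %in% reached]))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  expect_setequal(reached, 1:16)
})

test_that("network exports write DOT and CSV with all edges", {
  path <- tempfile(fileext = ".dot")
  write_network_dot(path, theta = default_theta_true())
  lines <- readLines(path)
  expect_length(grep("->", lines), 32L)
  unlink(path)
  csv <- tempfile(fileext = ".csv")
  write_network_csv(csv, theta = default_theta_true())
  edges <- read.csv(csv)
  expect_equal(nrow(edges), 32L)
  expect_equal(edges$rate[edges$from == 1 & edges$to == 5],
               default_theta_true()[["tubo"]])
  unlink(csv)
})
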