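# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: energies are summed pair by pair, and patch
# labelling is a plain flood fill.

# Total energy by explicit enumeration of all torus neighbour pairs
# (right and down neighbour of every cell = each unordered pair once).
energy_bruteforce <- function(states, B, J) {
  d <- nrow(states)
  pair_sum <- 0
  for (r in seq_len(d)) {
    for (c in seq_len(d)) {
      rt <- if (c == d) 1 else c + 1
      dn <- if (r == d) 1 else r + 1
      pair_sum <- pair_sum + states[r, c] * states[r, rt] +
        states[r, c] * states[dn, c]
    }
  }
  -J * pair_sum - B * sum(states)
}

# Connected components of +1 cells by flood fill on the plane (no wrap).
# Returns an integer label matrix, 0 = background.
floodfill_labels <- function(states, connectivity = 4) {
  nr <- nrow(states); nc <- ncol(states)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offsets <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      apply(1, identity, simplify = FALSE) |>
      Filter(f = function(o) any(o != 0))
  }
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (states[r0, c0] != 1 || lab[r0, c0] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- nxt
      while (length(queue) > 0) {
        cur <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (o in offsets) {
          rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
          if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
          if (states[rr, cc] == 1 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- nxt
            queue[[length(queue) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

# Partition of focus-cell indices induced by a labelling, in a canonical
# order, so two labelings can be compared irrespective of label numbering.
label_partition <- function(lab) {
  groups <- split(which(lab > 0), lab[lab > 0])
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, min, numeric(1)))] |> unname()
}

# Random landscape over {-1, +1} with i.i.d. cells (no exact count)
random_states <- function(d, p = 0.5) {
  matrix(sample(c(-1L, 1L), d * d, replace = TRUE, prob = c(1 - p, p)), d, d)
}
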