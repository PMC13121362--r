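# Connected-component labelling of 3-D binary arrays by vectorised min-label
# propagation. Neighbourhoods: 6 (faces), 18 (faces+edges), 26 (full cube).

neighbour_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1L, "18" = 2L, "26" = 3L)
  g[keep, , drop = FALSE]
}

# shift a 3-D array by integer offset, zero-filling exposed entries
shift3 <- function(a, off) {
  d <- dim(a)
  out <- array(0L, d)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(d[k] - o) + o; src[[k]] <- seq_len(d[k] - o) }
    else        { dst[[k]] <- seq_len(d[k] + o);     src[[k]] <- seq_len(d[k] + o) - o }
    if (length(dst[[k]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Label connected components of a binary 3-D array
#'
#' @param values binary 3-D array (numeric/logical/integer).
#' @param connectivity 6, 18 or 26 (default) neighbourhood.
#' @return Integer array of the same shape: 0 for background, 1..k component
#'   labels in order of first (column-major) occurrence.
#' @export
label_components <- function(values, connectivity = 26L) {
  d <- dim(values)
  fg <- values > 0
  lab <- array(0L, d)
  n_fg <- sum(fg)
  if (n_fg == 0) return(lab)
  lab[fg] <- which(fg)
  offs <- neighbour_offsets(as.integer(connectivity))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(offs))) {
      sh <- shift3(lab, offs[i, ])
      upd <- fg & sh > 0L & sh < lab
      if (any(upd)) { lab[upd] <- sh[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  # relabel to consecutive integers in order of first occurrence
  roots <- unique(lab[fg])
  relab <- integer(max(roots))
  relab[roots] <- seq_along(roots)
  lab[fg] <- relab[lab[fg]]
  lab
}
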