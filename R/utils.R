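# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frob <- function(x) sqrt(sum(Mod(x)^2))

stopifnot_even <- function(n, what) {
  if (n %% 2L != 0L) stop(what, " must be even, got ", n, call. = FALSE)
}

# Most frequent integer value; ties broken toward the smaller value.
int_mode <- function(x) {
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[tab == max(tab)][1L]
}

#' Label connected components of a binary image (4-connectivity)
#'
#' Flood-fill labelling of the TRUE pixels of a logical matrix using
#' 4-connectivity (edge-sharing neighbours only), the neighbourhood used for
#' cluster-extent rejection of activation maps.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 for background, components
#'   numbered from 1 in scan order.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1:2, 1] <- TRUE; m[4, 4] <- TRUE
#' label_components(m)
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (v - 1L) %% nr + 1L
      c <- (v - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) v - 1L, if (r < nr) v + 1L,
              if (c > 1L) v - nr, if (c < nc) v + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}
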