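#' Cluster compounds on a self-organizing map
#'
#' Standard online (Kohonen) SOM on a rectangular grid: codebook vectors
#' are initialized from a deterministic sample of the data, then updated
#' over `n_epochs` passes with a linearly decaying learning rate and a
#' Gaussian neighborhood whose radius shrinks from half the grid diagonal
#' to a single cell.  Each compound is finally assigned to the grid cell of
#' its best-matching unit; cells no compound maps to remain empty clusters.
#'
#' Any numeric per-compound feature matrix works as input — binary
#' structural fingerprints being the usual choice.  When cluster labels are
#' already available from other software they can be fed directly to
#' [cluster_enrichment()]; this function is not a required stage.
#'
#' @param fingerprints numeric matrix, one row per compound (row names are
#'   taken as compound ids).
#' @param grid c(rows, cols) of the map.
#' @param n_epochs passes over the data.
#' @param alpha c(start, end) learning rate, decayed linearly.
#' @param seed integer; fixes initialization and presentation order.
#' @return Data frame `compound_id`, `cluster_id` (`"r<row>c<col>"`).
#' @export
cluster_compounds <- function(fingerprints, grid = c(10L, 10L),
                              n_epochs = 20L, alpha = c(0.5, 0.01),
                              seed = 1L) {
  fingerprints <- as.matrix(fingerprints)
  n <- nrow(fingerprints)
  if (n == 0L) stop("no fingerprints supplied")
  ids <- rownames(fingerprints)
  if (is.null(ids)) ids <- sprintf("CMP%05d", seq_len(n))
  n_units <- grid[1] * grid[2]
  # grid coordinates of each unit, row-major
  coords <- cbind(rep(seq_len(grid[1]), times = grid[2]),
                  rep(seq_len(grid[2]), each = grid[1]))

  withr_seed(seed, {
    codes <- fingerprints[sample.int(n, n_units, replace = n < n_units), ,
                          drop = FALSE]
    codes <- codes + stats::rnorm(length(codes), 0, 1e-4) # break ties
    total <- n_epochs * n
    r0 <- sqrt(sum((grid - 1)^2)) / 2
    step <- 0L
    for (ep in seq_len(n_epochs)) {
      for (i in sample.int(n)) {
        step <- step + 1L
        frac <- step / total
        lr <- alpha[1] + (alpha[2] - alpha[1]) * frac
        radius <- max(r0 * (1 - frac), 0.5)
        x <- fingerprints[i, ]
        d2 <- rowSums(sweep(codes, 2, x)^2)
        bmu <- which.min(d2)
        gd2 <- (coords[, 1] - coords[bmu, 1])^2 +
          (coords[, 2] - coords[bmu, 2])^2
        h <- lr * exp(-gd2 / (2 * radius^2))
        upd <- h > 1e-4
        codes[upd, ] <- codes[upd, , drop = FALSE] +
          h[upd] * (matrix(x, sum(upd), ncol(codes), byrow = TRUE) -
                      codes[upd, , drop = FALSE])
      }
    }
    d <- apply(fingerprints, 1, function(x)
      which.min(rowSums(sweep(codes, 2, x)^2)))
    data.frame(compound_id = ids,
               cluster_id = sprintf("r%02dc%02d", coords[d, 1],
                                    coords[d, 2]),
               stringsAsFactors = FALSE)
  })
}

#' Test structural clusters for enrichment of active compounds
#'
#' For every cluster, the 2 x 2 table (in cluster vs rest of library,
#' active vs not) is tested with a one-sided Fisher's exact test for an
#' excess of actives over the library average.  No multiple-testing
#' correction is applied by default — each cluster is reported at its raw
#' p — but any method of [stats::p.adjust()] can be requested.
#'
#' @param assignments data frame `compound_id`, `cluster_id` covering the
#'   library.
#' @param active_flags named logical vector (names = compound ids), or an
#'   unnamed one aligned with `assignments`.
#' @param alpha significance level for the `enriched` flag.
#' @param p_adjust multiplicity correction method (default `"none"`).
#' @return Data frame `cluster_id`, `n_members`, `n_active`,
#'   `library_size`, `library_active`, `p_value`, `enriched`, sorted by
#'   p-value.
#' @examples
#' asg <- data.frame(compound_id = sprintf("C%02d", 1:40),
#'                   cluster_id = rep(c("k1", "k2"), each = 20))
#' act <- c(rep(TRUE, 8), rep(FALSE, 32))
#' cluster_enrichment(asg, act)
#' @export
cluster_enrichment <- function(assignments, active_flags, alpha = 0.05,
                               p_adjust = "none") {
  stopifnot(all(c("compound_id", "cluster_id") %in% names(assignments)))
  if (!is.null(names(active_flags))) {
    m <- match(assignments$compound_id, names(active_flags))
    if (anyNA(m)) stop("active_flags do not cover all assigned compounds")
    active <- as.logical(active_flags[m])
  } else {
    stopifnot(length(active_flags) == nrow(assignments))
    active <- as.logical(active_flags)
  }
  if (anyNA(active)) stop("active_flags contain missing values")

  n_lib <- nrow(assignments)
  n_act <- sum(active)
  rows <- lapply(split(seq_len(n_lib), assignments$cluster_id), function(ix) {
    k <- length(ix); a <- sum(active[ix])
    tab <- matrix(c(a, k - a, n_act - a, n_lib - k - (n_act - a)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(n_members = k, n_active = a, library_size = n_lib,
               library_active = n_act, p_value = p)
  })
  out <- do.call(rbind, rows)
  out <- cbind(cluster_id = names(rows), out)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$enriched <- out$p_value < alpha
  out <- out[order(out$p_value, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
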