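# Internal helpers shared across the pipeline.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Venetian-blind fold assignment: observation i (in the given order) goes to
# fold ((i - 1) mod folds) + 1.  An optional seed shuffles the order first so
# that fold membership is random but reproducible.
fold_assignment <- function(n, folds, seed = NULL) {
  stopifnot(folds >= 2, n >= folds)
  ord <- seq_len(n)
  if (!is.null(seed)) {
    ord <- with_seed(seed, sample.int(n))
  }
  id <- integer(n)
  id[ord] <- ((seq_len(n) - 1L) %% folds) + 1L
  id
}

# Connected components of an undirected graph given as a logical adjacency
# matrix (used for perfect-correlation and LD cliques); returns a membership
# vector of component ids.
graph_components <- function(adj) {
  m <- nrow(adj)
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cur
          nb <- which(adj[v, ] & comp == 0L)
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

is_dosage <- function(x) {
  all(is.na(x) | x %in% c(0, 1, 2))
}

check_genotype_matrix <- function(g) {
  if (!is.matrix(g) || !is.numeric(g)) {
    stop("genotypes must be a numeric matrix (participants x SNPs)",
         call. = FALSE)
  }
  if (nrow(g) < 1L || ncol(g) < 1L) {
    stop("genotype matrix is empty", call. = FALSE)
  }
  if (is.null(colnames(g)) || anyDuplicated(colnames(g))) {
    stop("genotype matrix needs unique SNP column names", call. = FALSE)
  }
  if (!is.null(rownames(g)) && anyDuplicated(rownames(g))) {
    stop("participant ids must be unique", call. = FALSE)
  }
  if (!is_dosage(g)) {
    stop("dosages must be 0, 1, 2 or NA (minor-allele counts)", call. = FALSE)
  }
  invisible(g)
}
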