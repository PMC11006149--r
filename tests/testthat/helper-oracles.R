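# Independent brute-force oracles used to validate the package's
# implementations. These are deliberately written as plain loops, separate
# from the vectorized code paths they check.

# L1 norm of a single activation map by explicit loop
oracle_l1_norm <- function(map) {
  s <- 0
  for (v in as.vector(map)) s <- s + abs(v)
  s
}

# per-kernel mean by explicit loop
oracle_col_means <- function(mat) {
  out <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    s <- 0
    for (i in seq_len(nrow(mat))) s <- s + mat[i, j]
    out[j] <- s / nrow(mat)
  }
  out
}

# elementwise strict-threshold binarization by explicit loop
oracle_binarize <- function(mat, theta) {
  out <- matrix(0, nrow(mat), ncol(mat))
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat)))
    out[i, j] <- if (mat[i, j] > theta[j]) 1 else -1
  out
}

# pixel-counting IOU for 0-based half-open integer boxes
oracle_iou_pixels <- function(a, b, size = 64) {
  grid_a <- matrix(FALSE, size, size)
  grid_b <- matrix(FALSE, size, size)
  grid_a[(a[2] + 1):a[4], (a[1] + 1):a[3]] <- TRUE
  grid_b[(b[2] + 1):b[4], (b[1] + 1):b[3]] <- TRUE
  inter <- sum(grid_a & grid_b)
  union <- sum(grid_a | grid_b)
  inter / union
}

# GLCM joint entropy by explicit pair enumeration (one angle offset)
oracle_glcm_entropy_angle <- function(lv, drow, dcol) {
  counts <- list()
  nr <- nrow(lv); nc <- ncol(lv)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + drow; j2 <- j + dcol
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
      for (key in c(paste(lv[i, j], lv[i2, j2]), paste(lv[i2, j2], lv[i, j]))) {
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  p <- unlist(counts)
  p <- p / sum(p)
  -sum(p * log2(p))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_glcm_entropy <- function(lv) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  mean(vapply(offs, function(o) oracle_glcm_entropy_angle(lv, o[1], o[2]),
              numeric(1)))
}

# run enumeration for one direction given as a list of line vectors
oracle_glrlm_lines <- function(lines) {
  runs <- list()   # list of c(gray, length)
  for (ln in lines) {
    if (!length(ln)) next
    cur <- ln[1]; len <- 1
    for (v in ln[-1]) {
      if (v == cur) len <- len + 1
      else { runs[[length(runs) + 1]] <- c(cur, len); cur <- v; len <- 1 }
    }
    runs[[length(runs) + 1]] <- c(cur, len)
  }
  runs
}

oracle_glrlm_nonuniformities <- function(lv) {
  nr <- nrow(lv); nc <- ncol(lv)
  dirs <- list(
    lapply(seq_len(nr), function(i) lv[i, ]),
    lapply(seq_len(nc), function(j) lv[, j]),
    lapply(seq(-(nr - 1), nc - 1), function(d) lv[row(lv) - col(lv) == -d]),
    lapply(seq(2, nr + nc), function(s) lv[row(lv) + col(lv) == s]))
  vals <- vapply(dirs, function(lines) {
    runs <- oracle_glrlm_lines(lines)
    g <- vapply(runs, `[`, numeric(1), 1)
    l <- vapply(runs, `[`, numeric(1), 2)
    nr_runs <- length(runs)
    c(sum(table(g)^2) / nr_runs, sum(table(l)^2) / nr_runs)
  }, numeric(2))
  c(gln = mean(vals[1, ]), rln = mean(vals[2, ]))
}

# exhaustive search over all depth-limited literal trees, returning the
# best achievable number of matches to the targets
oracle_best_tree_matches <- function(X, y, max_depth) {
  best <- function(rows, depth, used) {
    n1 <- sum(y[rows] == 1)
    leaf_best <- max(n1, length(rows) - n1)
    if (depth == 0 || length(rows) <= 1) return(leaf_best)
    b <- leaf_best
    for (k in setdiff(seq_len(ncol(X)), used)) {
      left <- rows[X[rows, k] == -1]
      right <- rows[X[rows, k] == 1]
      if (!length(left) || !length(right)) next
      v <- best(left, depth - 1, c(used, k)) +
           best(right, depth - 1, c(used, k))
      if (v > b) b <- v
    }
    b
  }
  best(seq_len(nrow(X)), max_depth, integer(0))
}

# small deterministic literal table fixture
random_literal_matrix <- function(n, k, seed) {
  set.seed(seed)
  matrix(sample(c(-1, 1), n * k, replace = TRUE), n, k)
}

# tiny phantom + trained model shared across model-dependent tests
.cnnrules_cache <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (is.null(.cnnrules_cache$model)) {
    cfg <- phantom_config(n_per_class = 40, seed = 7)
    ds <- generate_dataset(cfg)
    vcfg <- cfg
    vcfg$n_per_class <- 15L
    vcfg$seed <- 8L
    vds <- generate_dataset(vcfg)
    model <- train_tiny_cnn(ds, seed = 9, epochs = 8, val_dataset = vds,
                            min_val_acc = 0)
    .cnnrules_cache$model <- model
    .cnnrules_cache$train <- ds
    .cnnrules_cache$val <- vds
  }
  list(model = .cnnrules_cache$model, train = .cnnrules_cache$train,
       val = .cnnrules_cache$val)
}
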