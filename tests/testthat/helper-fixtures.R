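# Shared fixtures and independent oracles for the test suite.

# random valid percent composition (percentage points, sums to 100)
random_percent <- function() {
  p <- stats::runif(7, 0.5, 5)
  p <- 100 * p / sum(p)
  names(p) <- hand_areas()
  p
}

random_loads <- function() area_loads(stats::runif(1, 100, 500),
                                      random_percent())

# small simulated study shared across tests (2 sessions so sincere pairs
# exist); regenerated per test via the function so no cross-test state
tiny_study <- function(n = 6, seed = 11, model = effort_model()) {
  simulate_study(study_design(n_subjects = n, n_males = floor(n / 2),
                              n_right_handed = n, seed = seed), model)
}

# independent AUC oracle: Mann-Whitney probability over all pos/neg pairs,
# ties counted one half
u_auc <- function(scores, is_pos) {
  x <- scores[is_pos]; y <- scores[!is_pos]
  total <- 0
  for (a in x) total <- total + sum(a > y) + 0.5 * sum(a == y)
  total / (length(x) * length(y))
}

# brute-force per-area accumulation oracle for aggregate_map
brute_aggregate <- function(values, assignment) {
  sums <- setNames(numeric(7), hand_areas())
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      a <- assignment[i, j]
      if (!is.na(a)) sums[a] <- sums[a] + values[i, j]
    }
  }
  list(total = sum(sums), percent = 100 * sums / sum(sums))
}

# stratified bootstrap CI for the AUC (oracle for the DeLong interval)
boot_auc_ci <- function(scores, is_pos, reps = 2000, level = 0.95) {
  xi <- which(is_pos); yi <- which(!is_pos)
  stats <- replicate(reps, {
    bx <- sample(xi, length(xi), replace = TRUE)
    by <- sample(yi, length(yi), replace = TRUE)
    u_auc_fast(scores[c(bx, by)],
               c(rep(TRUE, length(bx)), rep(FALSE, length(by))))
  })
  stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                  names = FALSE)
}

# rank-based U statistic (fast version for the bootstrap)
u_auc_fast <- function(scores, is_pos) {
  r <- rank(scores)
  m <- sum(is_pos); n <- sum(!is_pos)
  (sum(r[is_pos]) - m * (m + 1) / 2) / (m * n)
}
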