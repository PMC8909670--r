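# Small cohort fixtures built in code; sizes chosen so the whole suite stays
# well inside the runtime budget.

blood_params <- c(a = 14.487, b = 0.019, c = 0.307, d = 0.105)

small_config <- function(n_samples = 120, n_sites = 200, noise_sd = 0.02,
                         seed = 101, ...) {
  sim_config(n_samples = n_samples, n_sites = n_sites, noise_sd = noise_sd,
             seed = seed, ...)
}

# full cohort beta matrix + matching truth states, in column order
cohort_matrix <- function(cohort) {
  B <- cbind(cohort$train$betas, cohort$validation$betas, cohort$test$betas)
  list(betas = B, states = cohort$truth$latent_states[colnames(B)],
       ages = c(cohort$train$ages, cohort$validation$ages, cohort$test$ages))
}

# toy dataset with exactly controllable values
toy_dataset <- function(betas, ages, probe_types = rep("I", nrow(betas))) {
  methylation_dataset(betas, ages, probe_types)
}

# enumerate all labeled spanning trees on k nodes via Pruefer sequences and
# return the minimum total Euclidean weight (independent MST oracle)
brute_force_mst_weight <- function(centers) {
  k <- nrow(centers)
  D <- as.matrix(dist(centers))
  if (k == 1) return(0)
  if (k == 2) return(D[1, 2])
  seqs <- expand.grid(rep(list(seq_len(k)), k - 2))
  tree_weight <- function(pruefer) {
    degree <- rep(1L, k)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    pr <- as.integer(pruefer)
    for (v in pr) {
      leaf <- min(which(degree == 1L))
      w <- w + D[leaf, v]
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    ends <- which(degree == 1L)
    w + D[ends[1], ends[2]]
  }
  min(apply(seqs, 1, tree_weight))
}
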