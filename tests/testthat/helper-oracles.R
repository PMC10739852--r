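# Brute-force flood-fill connected-component labeling: the independent
# oracle for label_components. Scans column-major, grows each component with
# an explicit stack. Intentionally naive.
flood_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 8L)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(0,-1), c(0,1), c(1,0))
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j)); lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in offs) {
          qi <- p[1] + o[1]; qj <- p[2] + o[2]
          if (qi >= 1 && qi <= H && qj >= 1 && qj <= W &&
              mask[qi, qj] && lab[qi, qj] == 0L) {
            lab[qi, qj] <- cur
            stack[[length(stack) + 1L]] <- c(qi, qj)
          }
        }
      }
    }
  }
  lab
}

# canonical renumbering by first (column-major) occurrence, for comparing
# labelings up to numbering
canon_labels <- function(lab) {
  v <- as.vector(lab)
  pos <- v > 0L
  u <- unique(v[pos])
  v[pos] <- match(v[pos], u)
  matrix(v, nrow(lab))
}

# quick record table builder for classification / quantification tests
make_records <- function(n = 1, area_px = 100L, mean_live = 1000,
                         mean_dead = 10, mean_ros = NA_real_,
                         viability = "unassigned",
                         ploidy_class = "unassigned", area_um2 = NA_real_) {
  data.frame(field_id = rep_len("f", n), label = seq_len(n),
             row = rep(0, n), col = rep(0, n),
             area_px = as.integer(rep_len(area_px, n)),
             area_um2 = rep_len(area_um2, n),
             mean_nuclei = rep_len(500, n),
             mean_live = rep_len(mean_live, n),
             mean_dead = rep_len(mean_dead, n),
             mean_ros = rep_len(mean_ros, n),
             viability = rep_len(viability, n),
             ploidy_class = rep_len(ploidy_class, n),
             solidity = rep_len(1, n), stringsAsFactors = FALSE)
}

# a small simulated field configuration used across tests (fast to render)
small_sim <- function(...) {
  sim_params(image_shape = c(384L, 384L), n_non_pgcc = 20L, n_pgcc = 4L,
             n_dead = 3L, n_debris = 3L, include_ros = FALSE, ...)
}
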