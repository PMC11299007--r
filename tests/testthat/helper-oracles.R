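# Independent oracles and fixture builders. These deliberately avoid the
# package's internal code paths: conflict sums use the literal double
# loop, and the Dempster oracle enumerates focal elements by brute force.

# Closed-form combination of exactly two weighted evidence bodies.
# p1, p2: belief vectors; w1, w2: weights already in [0, 1].
oracle_two_evidence <- function(p1, p2, w1, w2) {
  m1 <- w1 * p1; mt1 <- w1 * (1 - sum(p1)); mb1 <- 1 - w1
  m2 <- w2 * p2; mt2 <- w2 * (1 - sum(p2)); mb2 <- 1 - w2
  n <- length(p1)
  conflict <- 0
  for (a in seq_len(n)) for (b in seq_len(n))
    if (a != b) conflict <- conflict + m1[a] * m2[b]
  K <- 1 / (1 - conflict)
  mn <- K * (m1 * m2 + m1 * (mt2 + mb2) + m2 * (mt1 + mb1))
  mt <- K * (mt1 * mt2 + mb1 * mt2 + mt1 * mb2)
  mb <- K * (mb1 * mb2)
  list(beliefs = mn / (1 - mb), uncertainty = mt / (1 - mb), K = K,
       masses = list(m = mn, m_tilde = mt, m_bar = mb))
}

# Brute-force Dempster combination of two simple bodies (belief vectors +
# ignorance on the whole frame). Focal elements are indexed 1..n for the
# singletons and 0 for the frame; intersections are enumerated literally.
oracle_dempster_pair <- function(p1, p2) {
  n <- length(p1)
  f1 <- c(1 - sum(p1), p1)   # index 1 = frame, 1 + k = singleton k
  f2 <- c(1 - sum(p2), p2)
  acc <- numeric(n + 1)
  conflict <- 0
  for (a in 0:n) for (b in 0:n) {
    prod <- f1[a + 1] * f2[b + 1]
    inter <- if (a == 0) b else if (b == 0) a else if (a == b) a else -1
    if (inter < 0) conflict <- conflict + prod
    else acc[inter + 1] <- acc[inter + 1] + prod
  }
  if (1 - conflict <= 1e-12) return(NULL)  # undefined: complete conflict
  acc <- acc / (1 - conflict)
  list(beliefs = acc[-1], uncertainty = acc[1])
}

# A random belief vector on n propositions with ignorance <= inc_max.
random_beliefs <- function(n, inc_max = 0.3) {
  raw <- stats::rexp(n)
  (raw / sum(raw)) * (1 - stats::runif(1, 0, inc_max))
}

# --- directory-tree fixtures -------------------------------------------

grades5 <- c("Excellent", "Good", "Average", "Poor", "Worst")

write_node_csv <- function(path, objects, weight, beliefs, props) {
  df <- cbind(data.frame(Object = objects, Weight = weight),
              as.data.frame(beliefs))
  names(df) <- c("Object", "Weight", props)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

zero_mat <- function(objects, props)
  matrix(0, length(objects), length(props))

# Institution-shaped fixture: Objects/{Research,Teaching}/<4 leaves>, each
# leaf holding Student (weight 10) and Faculty (weight 8) evidence for
# objects D, E, F over five grades. Returns the root path.
make_institution_tree <- function(root_dir,
                                  objects = c("D", "E", "F"),
                                  props = grades5) {
  root <- file.path(root_dir, "Objects")
  leaves <- list(Research = c("Research_Funding", "Research_Outcomes"),
                 Teaching = c("Teaching_Materials", "Teaching_Methods"))
  dir.create(root, recursive = TRUE)
  write_node_csv(file.path(root, "Objects_combined.csv"), objects, 1,
                 zero_mat(objects, props), props)
  l <- 0L
  for (mid in names(leaves)) {
    mid_dir <- file.path(root, mid)
    dir.create(mid_dir)
    write_node_csv(file.path(mid_dir, paste0(mid, "_combined.csv")),
                   objects, 1, zero_mat(objects, props), props)
    for (leaf in leaves[[mid]]) {
      l <- l + 1L
      leaf_dir <- file.path(mid_dir, leaf)
      dir.create(leaf_dir)
      write_node_csv(file.path(leaf_dir, paste0(leaf, "_combined.csv")),
                     objects, 1, zero_mat(objects, props), props)
      for (s in 1:2) {
        tab <- generate_random_evidence(length(objects), length(props),
                                        seed = 100L * l + s,
                                        incompleteness_max = 0.2)
        beliefs <- do.call(rbind, lapply(tab$evidence, `[[`, "beliefs"))
        write_node_csv(
          file.path(leaf_dir,
                    sprintf("Evidence%d_%s.csv", s,
                            c("Student", "Faculty")[s])),
          objects, c(10, 8)[s], beliefs, props)
      }
    }
  }
  root
}

# Depth-1 fixture: root folder is itself a leaf with the given evidence
# rows (matrix) and per-evidence weights, for a single object.
make_flat_tree <- function(root_dir, beliefs, weights, props,
                           object = "Obj1") {
  root <- file.path(root_dir, "Objects")
  dir.create(root, recursive = TRUE)
  write_node_csv(file.path(root, "Objects_combined.csv"), object, 1,
                 matrix(0, 1, length(props)), props)
  for (i in seq_len(nrow(beliefs)))
    write_node_csv(file.path(root, sprintf("Evidence%d.csv", i)), object,
                   weights[i], beliefs[i, , drop = FALSE], props)
  root
}

# The worked three-expert diagnosis inputs, used across test files.
diagnosis_dbf <- function() {
  dbf <- rbind(c(0.9, 0, 0), c(0, 0.9, 0), c(0, 0, 0.9))
  colnames(dbf) <- c("Cold", "Common pneumonia", "COVID-19")
  dbf
}
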