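# Fixtures are built in code: small junctions for fast unit tests, the
# J34-sized junction where site counts matter, and template sets for
# rendering.

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# Random four-strand junction sequences complementary under the X-R-H-B arm
# scheme; the first base of each 3' half is fixed to C/A/C/A so the default
# core markers carry the canonical T/C (X, H) and A/G (R, B) identities.
make_sequences <- function(arm_length, seed = 1) {
  set.seed(seed)
  first <- c("C", "A", "C", "A")
  halves <- vapply(seq_len(4L), function(i) {
    paste(c(first[i], sample(c("A", "C", "G", "T"), arm_length - 1L, TRUE)),
          collapse = "")
  }, character(1L))
  c(X = paste0(revcomp(halves[4L]), halves[1L]),
    R = paste0(revcomp(halves[1L]), halves[2L]),
    H = paste0(revcomp(halves[2L]), halves[3L]),
    B = paste0(revcomp(halves[3L]), halves[4L]))
}

toy_topology <- function(arm_length = 3, seed = 1) {
  build_topology(make_sequences(arm_length, seed), arm_length)
}

j34_topology <- function() {
  build_topology(example_j34_sequences(), arm_length = 17)
}

template_set <- function(topology, open = "open-tetrahedral", iso2_ida = 90) {
  list("open" = idealized_geometry(topology, open),
       "iso-I" = idealized_geometry(topology, "iso-I"),
       "iso-II" = idealized_geometry(topology, "iso-II", nominal_ida = iso2_ida))
}

# independent truth-table classifier used as an oracle against classify_frame
oracle_classify <- function(tt, cc, ag1, ag2, cutoff = 12) {
  iso1_sig <- tt < cutoff && cc < cutoff
  iso2_sig <- ag1 < cutoff && ag2 < cutoff
  if (iso1_sig && iso2_sig) return("ambiguous")
  if (iso1_sig) return("iso-I")
  if (iso2_sig) return("iso-II")
  "open"
}

random_rigid_motion <- function(frame, seed = 1) {
  set.seed(seed)
  q <- rnorm(4L); q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  rot <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                  2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                  2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                3L, 3L, byrow = TRUE)
  sweep(frame %*% t(rot), 2L, -runif(3L, -100, 100))
}
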