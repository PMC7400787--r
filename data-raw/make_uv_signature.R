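# Generates inst/extdata/uv_signature_synthetic_192.tsv
#
# The package needs a strand-resolved (192-channel) UV substitution signature.
# The published strand-resolved table is not redistributable here, so a
# synthetic stand-in is constructed from the qualitative physics of UV
# mutagenesis and pinned to the one probability that is public:
#
#   * C>T transitions at dipyrimidine sites (5' neighbour T or C) dominate;
#     the TCC>TTC channel -- the most frequent UV-induced substitution -- is
#     pinned at probability 0.2887.
#   * Minor contributions from T>C / T>A at dipyrimidines and a small
#     residue of all remaining channel types, so all 192 channels are
#     represented.
#   * Transcription-coupled repair biases mutations away from the
#     purine-reference (reciprocal-strand) representation; each
#     purine-reference channel carries rho = 0.25 of the weight of its
#     pyrimidine-reference complement.
#
# Relative weights below shape everything except the pinned channel pair;
# the pinned pair takes 0.2887 (+ rho * 0.2887 on its complement) and the
# remaining mass is distributed over the other 190 channels in proportion
# to weight. Deterministic; re-running reproduces the file byte-for-byte.

bases <- c("A", "C", "G", "T")
comp <- c(A = "T", C = "G", G = "C", T = "A")
rho <- 0.25

fwd_weight <- function(c5, ref, alt, c3) {
  if (ref == "C" && alt == "T") {
    if (c5 == "T") return(c(A = 45, C = 100, G = 30, T = 90)[[c3]])
    if (c5 == "C") return(c(A = 30, C = 65, G = 20, T = 60)[[c3]])
    return(4)                       # non-dipyrimidine C>T
  }
  # non-C>T channels carry ~5% of forward mass in total, matching the
  # documented dominance (~95%) of C>T in the UV signature
  if (ref == "T" && alt == "C") return(if (c5 %in% c("C", "T")) 1.2 else 0.2)
  if (ref == "T" && alt == "A") return(if (c5 %in% c("C", "T")) 0.6 else 0.1)
  if (ref == "C" && alt == "A") return(0.2)
  if (ref == "C" && alt == "G") return(0.1)
  if (ref == "T" && alt == "G") return(0.1)
  stop("unexpected reference base")
}

rows <- list()
for (c5 in bases) for (ref in c("C", "T"))
  for (alt in setdiff(bases, ref)) for (c3 in bases) {
    w <- fwd_weight(c5, ref, alt, c3)
    rows[[length(rows) + 1]] <-
      data.frame(ctx5 = c5, ref = ref, alt = alt, ctx3 = c3, w = w)
    rows[[length(rows) + 1]] <-
      data.frame(ctx5 = comp[[c3]], ref = comp[[ref]], alt = comp[[alt]],
                 ctx3 = comp[[c5]], w = rho * w)
  }
sig <- do.call(rbind, rows)
stopifnot(nrow(sig) == 192,
          !anyDuplicated(with(sig, paste(ctx5, ref, alt, ctx3))))

pin    <- with(sig, ctx5 == "T" & ref == "C" & alt == "T" & ctx3 == "C")
pin_rc <- with(sig, ctx5 == "G" & ref == "G" & alt == "A" & ctx3 == "A")
p <- numeric(nrow(sig))
p[pin] <- 0.2887
p[pin_rc] <- rho * 0.2887
rest <- !(pin | pin_rc)
p[rest] <- sig$w[rest] / sum(sig$w[rest]) * (1 - sum(p))
sig$prob <- p
stopifnot(abs(sum(sig$prob) - 1) < 1e-12)

sig <- sig[order(sig$ctx5, sig$ref, sig$alt, sig$ctx3),
           c("ctx5", "ref", "alt", "ctx3", "prob")]

out <- file.path("inst", "extdata", "uv_signature_synthetic_192.tsv")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
con <- file(out, "w")
writeLines(c(
  "# Synthetic strand-resolved UV substitution signature (192 channels).",
  "# Constructed stand-in for a published UV signature: C>T at dipyrimidine",
  "# contexts dominates; TCC>TTC pinned at the published probability 0.2887;",
  "# purine-reference (reciprocal-strand) channels down-weighted by 0.25.",
  "# Generated by data-raw/make_uv_signature.R. NOT a published table."),
  con)
write.table(data.frame(sig[1:4],
                       prob = formatC(sig$prob, digits = 17, format = "g")),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
cat("wrote", out, "\n")
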