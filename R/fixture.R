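# Synthetic germline reference generator.
#
# Emulates the structure of an immunoglobulin heavy-chain reference
# directory at a scale where every component of the classifier can be
# exercised without external downloads: small families of related V "genes"
# with a known phylogeny, short J genes carrying the conserved Trp / [FW]G.G
# and TVSS motifs, and a dictionary of short D segments. Sequences are
# evolved along a fixed family > gene > allele hierarchy, so the true tree
# and the naming hierarchy agree by construction.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_codon <- function() {
  repeat {
    cod <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
    if (!cod %in% STOP_CODONS) return(cod)
  }
}

# mutate n random positions, never touching `protect` (1-based positions)
# and never creating an in-frame stop codon (frame 0)
mutate_keep_frame <- function(seq, n, protect = integer()) {
  cc <- chars(seq)
  ok <- setdiff(seq_along(cc), protect)
  tries <- 0
  while (n > 0 && tries < 1000) {
    tries <- tries + 1
    pos <- sample(ok, 1)
    old <- cc[pos]
    cc[pos] <- sample(setdiff(BASES, old), 1)
    cstart <- pos - (pos - 1) %% 3
    if (cstart + 2 <= length(cc) &&
        paste(cc[cstart:(cstart + 2)], collapse = "") %in% STOP_CODONS) {
      cc[pos] <- old
    } else {
      n <- n - 1
    }
  }
  paste(cc, collapse = "")
}

#' Generate a synthetic germline reference set
#'
#' Produces aligned V genes (`n_families` x `genes_per_family` x
#' `alleles_per_gene`), J genes (2 genes x 2 alleles) with the conserved
#' motifs in place, and a small D dictionary, together with the true V and J
#' topologies and the V region boundary table. The V alignment is gap-free
#' and codon-aligned by construction; region boundaries follow the usual
#' FR1-CDR1-FR2-CDR2-FR3 layout with the FW3 3' cysteine as the last FR3
#' codon, followed by a two-codon V tail that seeds the CDR3.
#'
#' @param n_families,genes_per_family,alleles_per_gene V hierarchy sizes
#' @param n_d_genes,d_alleles_per_gene D dictionary sizes
#' @param seed RNG seed; the generator is fully deterministic given it
#' @return list with FASTA texts (`v_fasta`, `d_fasta`, `j_fasta`), newick
#'   strings of the true topologies (`v_tree`, `j_tree`), the boundary
#'   configuration (`config`) and the raw sequence tables
#' @export
synthetic_germline <- function(n_families = 3, genes_per_family = 3,
                               alleles_per_gene = 2, n_d_genes = 3,
                               d_alleles_per_gene = 2, seed = 42) {
  with_seed(seed, {
    # --- V: 96 codons; FR/CDR boundaries in 0-based half-open columns
    n_codons <- 96
    cys_codon <- 93                       # FW3 3' Cys, 0-based codon index
    boundaries <- list(FR1 = c(0, 75), CDR1 = c(75, 99), FR2 = c(99, 150),
                       CDR2 = c(150, 174), FR3 = c(174, 282))
    root <- paste(replicate(n_codons, random_codon()), collapse = "")
    cys_cols <- (cys_codon * 3 + 1):(cys_codon * 3 + 3)   # 1-based protect
    root <- paste0(substr(root, 1, cys_codon * 3), "TGT",
                   substr(root, cys_codon * 3 + 4, n_codons * 3))
    v <- list()
    for (f in seq_len(n_families)) {
      fam_seq <- mutate_keep_frame(root, 40, cys_cols)
      for (g in seq_len(genes_per_family)) {
        gene_seq <- mutate_keep_frame(fam_seq, 14, cys_cols)
        for (a in seq_len(alleles_per_gene)) {
          # every allele carries private substitutions so that tips are
          # distinct from reconstructed gene ancestors (as in real
          # references after duplicate filtering)
          al_seq <- mutate_keep_frame(gene_seq, a + 1, cys_cols)
          name <- sprintf("IGHV%d-%d*%02d", f, g, a)
          v[[name]] <- al_seq
        }
      }
    }
    v_tree <- paste0("(", paste(vapply(seq_len(n_families), function(f) {
      paste0("(", paste(vapply(seq_len(genes_per_family), function(g) {
        paste0("(", paste(sprintf("IGHV%d-%d*%02d", f, g,
                                  seq_len(alleles_per_gene)),
                          collapse = ","), ")")
      }, character(1)), collapse = ","), ")")
    }, character(1)), collapse = ","), ");")

    # --- J: 15 nt head + WGQG...TVSS tail (11 codons), 48 nt total
    j_tail <- "TGGGGCCAAGGGACCACGGTCACCGTCTCCTCA"  # W G Q G T T V T V S S
    protect_tail <- 15 + c(1:12, 22:33)            # WGQG and TVSS codons
    j_root <- paste0(paste(replicate(5, random_codon()), collapse = ""), j_tail)
    j <- list()
    for (g in 1:2) {
      gene_seq <- mutate_keep_frame(j_root, 5, protect_tail)
      for (a in 1:2) {
        al_seq <- mutate_keep_frame(gene_seq, a, protect_tail)
        j[[sprintf("IGHJ%d*%02d", g, a)]] <- al_seq
      }
    }
    j_tree <- paste0("(",
      paste(vapply(1:2, function(g)
        paste0("(", sprintf("IGHJ%d*01", g), ",", sprintf("IGHJ%d*02", g), ")"),
        character(1)), collapse = ","), ");")

    # --- D: short segments
    d <- list()
    for (g in seq_len(n_d_genes)) {
      len <- sample(11:17, 1)   # real D segments are short
      gene_seq <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      for (a in seq_len(d_alleles_per_gene)) {
        al_seq <- if (a == 1) gene_seq else {
          pos <- sample(len, 1)
          cc <- chars(gene_seq)
          cc[pos] <- sample(setdiff(BASES, cc[pos]), 1)
          paste(cc, collapse = "")
        }
        d[[sprintf("IGHD%d-%d*%02d", g, g, a)]] <- al_seq
      }
    }

    fasta_of <- function(seqs, type) {
      unlist(lapply(names(seqs), function(n)
        c(sprintf(">SYN%s|%s|Synthetica|F|%s-REGION", n, n, type), seqs[[n]])))
    }
    list(v_fasta = fasta_of(v, "V"), d_fasta = fasta_of(d, "D"),
         j_fasta = fasta_of(j, "J"),
         v_tree = v_tree, j_tree = j_tree,
         v_seqs = unlist(v), d_seqs = unlist(d), j_seqs = unlist(j),
         config = list(v_boundaries = boundaries,
                       v_cys_column = cys_codon * 3,
                       j_trp_column = 15,
                       provenance = sprintf("synthetic_germline(seed=%d)", seed)))
  })
}

#' Build a ready-to-use classifier bundle from the synthetic reference
#'
#' Convenience wrapper: runs [synthetic_germline()] and [build_bundle()] with
#' the true topologies supplied.
#'
#' @param seed passed to [synthetic_germline()]
#' @param ... further arguments to [synthetic_germline()]
#' @return a `vdj_bundle`
#' @export
synthetic_bundle <- function(seed = 42, ...) {
  g <- synthetic_germline(seed = seed, ...)
  build_bundle(g$v_fasta, g$j_fasta, g$d_fasta, config = g$config,
               v_tree = g$v_tree, j_tree = g$j_tree)
}
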