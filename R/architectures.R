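.sources <- c("TargetScan", "miRanda", "both")

#' Validate a miRNA -> target-gene prediction table
#'
#' @param table Data frame with columns `mirna_id`, `gene_id`, `source`
#'   (one of `"TargetScan"`, `"miRanda"`, `"both"`).
#' @return The validated table with character columns.
#' @export
validate_target_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("mirna_id", "gene_id", "source")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) {
    stop("target table lacks column(s): ", paste(miss, collapse = ", "))
  }
  table$mirna_id <- as.character(table$mirna_id)
  table$gene_id <- as.character(table$gene_id)
  table$source <- as.character(table$source)
  if (any(!table$source %in% .sources)) {
    stop("target table source must be one of: ",
         paste(.sources, collapse = ", "))
  }
  if (anyDuplicated(paste(table$mirna_id, table$gene_id, sep = "\r")) > 0L) {
    stop("target table has duplicated (mirna_id, gene_id) entries")
  }
  table
}

#' Read a miRNA target table from delimited text
#'
#' @param path Path to a file with columns `mirna_id`, `gene_id`, `source`.
#' @return Validated target table.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_target_table(utils::read.table(path, header = TRUE,
                                          sep = .delim_for(path),
                                          stringsAsFactors = FALSE))
}

#' Write a miRNA target table to delimited text
#'
#' @param table Target table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_table <- function(table, path) {
  table <- validate_target_table(table)
  utils::write.table(table, path, sep = .delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Retain the candidate miRNA-gene pairs present in the target table
#'
#' Filters the cross product of the supplied miRNAs and genes down to the
#' pairs predicted by the table, in deterministic (gene, then miRNA)
#' lexicographic order.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param genes Character vector of gene ids.
#' @param table Target table (see [validate_target_table()]).
#' @return Data frame with columns `mirna_id`, `gene_id`.
#' @export
filter_target_pairs <- function(mirnas, genes, table) {
  table <- validate_target_table(table)
  keep <- table$mirna_id %in% mirnas & table$gene_id %in% genes
  pairs <- table[keep, c("mirna_id", "gene_id"), drop = FALSE]
  pairs <- pairs[order(pairs$gene_id, pairs$mirna_id), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Validate a transcription-factor configuration
#'
#' A TF configuration maps each downstream gene to its repressor proteins,
#' its activator-protein pool, and a combination mode: `"fixed"` (one
#' architecture per pair, with the listed proteins) or
#' `"all_nonempty_subsets"` (one architecture per nonempty subset of the
#' activator pool). Repressors and activators must be disjoint per gene.
#'
#' @param config Named list; each element a list with fields `repressors`,
#'   `activators`, `mode`.
#' @return The validated configuration.
#' @export
validate_tf_config <- function(config) {
  stopifnot(is.list(config), length(names(config)) == length(config))
  for (gene in names(config)) {
    entry <- config[[gene]]
    entry$repressors <- as.character(entry$repressors %||% character())
    entry$activators <- as.character(entry$activators %||% character())
    entry$mode <- entry$mode %||% "fixed"
    if (!entry$mode %in% c("fixed", "all_nonempty_subsets")) {
      stop("tf config for gene '", gene, "': unknown mode '", entry$mode, "'")
    }
    if (length(intersect(entry$repressors, entry$activators)) > 0L) {
      stop("tf config for gene '", gene,
           "': repressors and activators must be disjoint")
    }
    config[[gene]] <- entry
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a transcription-factor configuration from YAML
#'
#' @param path YAML file keyed by gene, each entry with `repressors`,
#'   `activators` and `mode` fields.
#' @return Validated TF configuration list.
#' @export
read_tf_config <- function(path) {
  validate_tf_config(yaml::read_yaml(path))
}

#' Write a transcription-factor configuration as YAML
#'
#' @param config TF configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_config <- function(config, path) {
  yaml::write_yaml(validate_tf_config(config), path)
  invisible(path)
}

#' Construct a transcription-degradation architecture
#'
#' A small interaction network in which one or more miRNAs degrade the
#' downstream mRNA gene directly, while repressor and activator proteins
#' control its transcription through Hill-type impacts.
#'
#' @param gene Downstream mRNA gene id.
#' @param mirnas Nonempty character vector of degrading miRNA ids.
#' @param rep_proteins Transcriptional repressor protein ids.
#' @param act_proteins Transcriptional activator protein ids (disjoint from
#'   the repressors).
#' @return Object of class `transcr_degr_arch`.
#' @export
transcr_degr_arch <- function(gene, mirnas, rep_proteins = character(),
                              act_proteins = character()) {
  mirnas <- as.character(mirnas)
  rep_proteins <- as.character(rep_proteins)
  act_proteins <- as.character(act_proteins)
  if (length(mirnas) == 0L) stop("a Transcr.Degr. architecture needs >= 1 miRNA")
  if (length(intersect(rep_proteins, act_proteins)) > 0L) {
    stop("repressor and activator protein sets must be disjoint")
  }
  n_prot <- length(rep_proteins) + length(act_proteins)
  if (n_prot < 1L || n_prot > 6L) {
    stop("a Transcr.Degr. architecture needs 1..6 transcription-factor ",
         "proteins (parameter count 5..15); got ", n_prot)
  }
  structure(list(gene = as.character(gene), mirnas = mirnas,
                 rep_proteins = rep_proteins, act_proteins = act_proteins),
            class = c("transcr_degr_arch", "cke_arch"))
}

#' Construct a translation-inhibition architecture
#'
#' A network in which 1-3 miRNAs inhibit translation of the downstream
#' protein produced by a gene, without degrading the mRNA itself.
#'
#' @param gene mRNA gene id (its profile drives translation).
#' @param protein Downstream protein id produced by `gene`.
#' @param mirnas Nonempty character vector of inhibiting miRNA ids.
#' @return Object of class `transl_inhib_arch`.
#' @export
transl_inhib_arch <- function(gene, protein, mirnas) {
  mirnas <- as.character(mirnas)
  if (length(mirnas) == 0L) stop("a Transl.Inhib. architecture needs >= 1 miRNA")
  structure(list(gene = as.character(gene), protein = as.character(protein),
                 mirnas = mirnas),
            class = c("transl_inhib_arch", "cke_arch"))
}

#' Canonical identifier of an architecture
#'
#' @param arch A `cke_arch` object.
#' @return Deterministic id string encoding kind, gene and regulators.
#' @export
arch_id <- function(arch) {
  if (inherits(arch, "transcr_degr_arch")) {
    paste0("TD:", arch$gene, ":", paste(arch$mirnas, collapse = "+"),
           "|rep=", paste(arch$rep_proteins, collapse = "+"),
           "|act=", paste(arch$act_proteins, collapse = "+"))
  } else if (inherits(arch, "transl_inhib_arch")) {
    paste0("TI:", arch$gene, ">", arch$protein, ":",
           paste(arch$mirnas, collapse = "+"))
  } else {
    stop("not a cke_arch object")
  }
}

#' Number of fitted kinetic parameters of an architecture
#'
#' Transcription-degradation: two Hill parameters per transcription-factor
#' protein plus the three rates (transcription, miRNA reaction,
#' degradation). Translation-inhibition: two Hill parameters per miRNA plus
#' the translation rate (the protein decay rate is pre-estimated, not
#' fitted).
#'
#' @param arch A `cke_arch` object.
#' @return Integer parameter count.
#' @export
n_params <- function(arch) UseMethod("n_params")

#' @export
n_params.transcr_degr_arch <- function(arch) {
  2L * (length(arch$rep_proteins) + length(arch$act_proteins)) + 3L
}

#' @export
n_params.transl_inhib_arch <- function(arch) {
  2L * length(arch$mirnas) + 1L
}

#' @export
print.cke_arch <- function(x, ...) {
  cat(arch_id(x), " (", n_params(x), " parameters)\n", sep = "")
  invisible(x)
}

.nonempty_subsets <- function(pool) {
  pool <- sort(pool)
  out <- list()
  for (k in seq_along(pool)) {
    cmb <- utils::combn(pool, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Build the family of transcription-degradation architectures
#'
#' For each retained (miRNA, gene) pair, genes configured in
#' `all_nonempty_subsets` mode yield one architecture per nonempty subset
#' of their activator pool (with the configured repressors always
#' included); genes in `fixed` mode yield exactly one architecture with the
#' configured protein lists. Each constructed architecture carries exactly
#' one miRNA.
#'
#' @param pairs Data frame of retained pairs, as from
#'   [filter_target_pairs()].
#' @param tf_config TF configuration (see [validate_tf_config()]).
#' @return List of `transcr_degr_arch` objects in deterministic order
#'   (pair order, then subset size, then lexicographic).
#' @export
build_transcr_degr_family <- function(pairs, tf_config) {
  tf_config <- validate_tf_config(tf_config)
  missing_genes <- setdiff(unique(pairs$gene_id), names(tf_config))
  if (length(missing_genes) > 0L) {
    stop("configuration error: no TF configuration for gene(s): ",
         paste(missing_genes, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    gene <- pairs$gene_id[i]
    mirna <- pairs$mirna_id[i]
    cfg <- tf_config[[gene]]
    if (cfg$mode == "all_nonempty_subsets") {
      for (sub in .nonempty_subsets(cfg$activators)) {
        out[[length(out) + 1L]] <- transcr_degr_arch(
          gene, mirna, rep_proteins = cfg$repressors, act_proteins = sub)
      }
    } else {
      out[[length(out) + 1L]] <- transcr_degr_arch(
        gene, mirna, rep_proteins = cfg$repressors,
        act_proteins = cfg$activators)
    }
  }
  out
}

#' Build the family of translation-inhibition architectures
#'
#' All subsets of the candidate miRNAs of size 1 up to
#' `min(max_combo, n_candidates)`, each defining one architecture. Subsets
#' are enumerated in deterministic order: by size, then lexicographically.
#'
#' @param gene mRNA gene id.
#' @param protein Downstream protein id produced by `gene`.
#' @param candidate_mirnas Character vector of miRNAs targeting `gene`.
#' @param max_combo Maximum number of miRNAs per architecture (>= 1).
#' @return List of `transl_inhib_arch` objects; empty when there are no
#'   candidates.
#' @export
build_transl_inhib_family <- function(gene, protein, candidate_mirnas,
                                      max_combo = 3L) {
  if (max_combo < 1L) stop("max_combo must be >= 1")
  candidate_mirnas <- sort(unique(as.character(candidate_mirnas)))
  n <- length(candidate_mirnas)
  if (n == 0L) return(list())
  out <- list()
  for (k in seq_len(min(max_combo, n))) {
    for (sub in utils::combn(candidate_mirnas, k, simplify = FALSE)) {
      out[[length(out) + 1L]] <- transl_inhib_arch(gene, protein, sub)
    }
  }
  out
}

#' miRNA-gene pairs embedded in an architecture
#'
#' @param arch A `cke_arch` object.
#' @return Data frame with columns `mirna_id`, `gene_id`, `kind`.
#' @export
arch_pairs <- function(arch) {
  kind <- if (inherits(arch, "transcr_degr_arch")) "Transcr.Degr." else "Transl.Inhib."
  data.frame(mirna_id = arch$mirnas, gene_id = arch$gene, kind = kind,
             stringsAsFactors = FALSE)
}
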