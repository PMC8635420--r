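#' CTD residue grouping scheme
#'
#' Seven physicochemical properties, each partitioning the 20 standard amino
#' acids into three disjoint classes: hydrophobicity, normalized van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, and solvent accessibility.  These are the standard partitions
#' used by sequence-descriptor packages; they are embedded verbatim so the
#' descriptor definition is pinned, and the cover/disjointness invariant is
#' enforced on access.
#'
#' @return Named list of 7 properties; each a character vector of 3 class
#'   strings whose residues cover the 20-letter alphabet exactly once.
#' @export
ctd_groups <- function() {
  groups <- list(
    hydrophobicity        = c("RKEDQN",   "GASTPHY",          "CLVIMFW"),
    vdw_volume            = c("GASTPDC",  "NVEQIL",           "MHKFRYW"),
    polarity              = c("LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability        = c("GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge                = c("KR",       "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure   = c("EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_accessibility = c("ALFCGIVW", "RKQEND",           "MSPTHY"))
  for (p in names(groups)) {
    residues <- sort(unlist(strsplit(groups[[p]], "")))
    if (!identical(residues, sort(unlist(strsplit("ACDEFGHIKLMNPQRSTVWY", ""))))) {
      stop("ctd_groups(): classes of '", p,
           "' do not partition the 20 standard residues", call. = FALSE)
    }
  }
  groups
}

#' Composition/Transition/Distribution (CTD) protein descriptors
#'
#' 147 sequence features: for each of the 7 physicochemical properties in
#' [ctd_groups()] (3 residue classes each),
#' * Composition (3): class fraction `n_g / N`;
#' * Transition (3): for each unordered class pair \{g, h\}, the fraction of
#'   adjacent residue pairs that switch between the classes,
#'   `(n_gh + n_hg) / (N - 1)`;
#' * Distribution (15): the 1-based sequence position, divided by N, of the
#'   first, 25\%, 50\%, 75\% and last residue of each class, where the q-th
#'   quantile slot is the position of the `ceiling(q * n_g)`-th occurrence;
#'   absent classes contribute 0 in all five slots.
#'
#' @param sequence Amino-acid string of length >= 2 over the 20 standard
#'   one-letter codes (case-insensitive).
#' @return Named numeric vector of length 147, blocks ordered property-major
#'   as `<property>.{C1..C3, T12, T13, T23, D<class>.<q>}`.
#' @export
#' @examples
#' length(ctd_descriptors("MKVLA"))  # 147
ctd_descriptors <- function(sequence) {
  sequence <- toupper(sequence)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (n < 2) stop("ctd_descriptors(): sequence must have length >= 2",
                  call. = FALSE)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!(res %in% alphabet))
  if (length(bad) > 0) {
    stop("ctd_descriptors(): non-standard residue '", res[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  groups <- ctd_groups()
  out <- double(0)
  for (p in names(groups)) {
    # map residues to classes 1..3
    cls_map <- stats::setNames(rep(NA_integer_, 20), alphabet)
    for (g in 1:3) {
      cls_map[strsplit(groups[[p]][g], "")[[1]]] <- g
    }
    cls <- unname(cls_map[res])
    # Composition
    comp <- tabulate(cls, 3) / n
    # Transition: unordered adjacent class switches
    a <- cls[-n]; b <- cls[-1]
    trans <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
               sum((a == 1 & b == 3) | (a == 3 & b == 1)),
               sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (n - 1)
    # Distribution
    distr <- double(15)
    for (g in 1:3) {
      pos <- which(cls == g)
      ng <- length(pos)
      if (ng > 0) {
        picks <- c(1, ceiling(c(0.25, 0.5, 0.75) * ng), ng)
        distr[(g - 1) * 5 + 1:5] <- pos[picks] / n
      }
    }
    block <- c(comp, trans, distr)
    names(block) <- paste0(p, ".",
                           c(paste0("C", 1:3), "T12", "T13", "T23",
                             paste0("D", rep(1:3, each = 5), ".",
                                    rep(c("first", "q25", "q50", "q75", "last"), 3))))
    out <- c(out, block)
  }
  out
}

#' Hashed circular (Morgan-style) fingerprint from SMILES
#'
#' Parses the SMILES through the configured cheminformatics backend
#' (ChemmineR/ChemmineOB by default), then iteratively hashes each atom's
#' circular neighborhood: the radius-0 invariant combines element, degree,
#' attached-hydrogen-free heavy degree and ring-bond count proxy (charge
#' column of the atom block), and each further radius folds in the sorted
#' (bond order, neighbor invariant) pairs.  Every invariant at every radius
#' sets one bit modulo `n_bits`.  Deterministic: identical input gives
#' identical bits.  Precomputed feature tables ([read_feature_table()])
#' bypass this entirely, so the chemistry backend is optional at run time.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (default 2, i.e. ECFP4-like).
#' @param n_bits Fingerprint length (default 2048, >= 8).
#' @param backend Function `smiles -> list(elements, bonds)` where `elements`
#'   is a character vector of atom symbols and `bonds` a 3-column matrix
#'   (atom1, atom2, order); defaults to the ChemmineR parser.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
circular_fingerprint <- function(smiles, radius = 2, n_bits = 2048,
                                 backend = chemminer_backend) {
  stopifnot(length(smiles) == 1, radius >= 0, n_bits >= 8)
  mol <- backend(smiles)
  n_atom <- length(mol$elements)
  if (n_atom == 0) {
    stop("circular_fingerprint(): cannot parse SMILES '", smiles, "'",
         call. = FALSE)
  }
  bonds <- mol$bonds
  nb <- vector("list", n_atom)
  bond_order <- vector("list", n_atom)
  if (!is.null(bonds) && nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      a <- bonds[i, 1]; b <- bonds[i, 2]; o <- bonds[i, 3]
      nb[[a]] <- c(nb[[a]], b); bond_order[[a]] <- c(bond_order[[a]], o)
      nb[[b]] <- c(nb[[b]], a); bond_order[[b]] <- c(bond_order[[b]], a * 0 + o)
    }
  }
  degree <- lengths(nb)
  elem_code <- as.integer(factor(mol$elements,
                                 levels = sort(unique(mol$elements))))
  # radius-0 invariant: element identity is hashed from its symbol so codes
  # do not depend on which other elements happen to be present
  sym_hash <- purrr::map_dbl(mol$elements, ~ int_hash(utf8ToInt(.x)))
  inv <- purrr::map_dbl(seq_len(n_atom),
                        ~ int_hash(c(sym_hash[.x], degree[.x])))
  feats <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_inv <- purrr::map_dbl(seq_len(n_atom), function(a) {
        if (degree[a] == 0) return(int_hash(c(r, inv[a])))
        pairs <- cbind(bond_order[[a]], inv[nb[[a]]])
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        int_hash(c(r, inv[a], as.vector(t(pairs))))
      })
      inv <- new_inv
      feats <- c(feats, inv)
    }
  }
  bits <- integer(n_bits)
  bits[(feats %% n_bits) + 1] <- 1L
  bits
}

# Deterministic integer-sequence hash (31-ary polynomial over a Mersenne
# prime); doubles stay well below 2^53 so arithmetic is exact.
int_hash <- function(xs) {
  h <- 2166136261
  m <- 2147483647
  for (x in xs) {
    h <- (h * 31 + (x %% m)) %% m
  }
  h
}

# default SMILES backend: ChemmineR + ChemmineOB
chemminer_backend <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("circular_fingerprint(): the ChemmineR/ChemmineOB backend is not ",
         "installed; supply a precomputed feature table instead", call. = FALSE)
  }
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  bad <- inherits(sdf, "try-error") || length(sdf) == 0
  if (!bad) {
    ab <- ChemmineR::atomblock(sdf[[1]])
    # the converter signals failure with a malformed atom block
    bad <- nrow(ab) == 0 || !all(grepl("^[A-Za-z]+_[0-9]+$", rownames(ab)))
  }
  if (bad) {
    stop("circular_fingerprint(): cannot parse SMILES '", smiles, "'",
         call. = FALSE)
  }
  bb <- ChemmineR::bondblock(sdf[[1]])
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0) NULL else
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  list(elements = elements, bonds = bonds)
}

#' Fingerprint a table of drugs
#'
#' @param drugs Tibble with columns `id`, `smiles`.
#' @param radius,n_bits,backend See [circular_fingerprint()].
#' @return A feature table (tibble, `id` + `fp1..fp<n_bits>`).
#' @export
fingerprint_table <- function(drugs, radius = 2, n_bits = 2048,
                              backend = chemminer_backend) {
  rows <- purrr::map(seq_len(nrow(drugs)), function(i) {
    bits <- tryCatch(
      circular_fingerprint(drugs$smiles[i], radius, n_bits, backend),
      error = function(e) stop("fingerprint_table(): entity '", drugs$id[i],
                               "': ", conditionMessage(e), call. = FALSE))
    bits
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("fp", seq_len(n_bits))
  dplyr::bind_cols(tibble::tibble(id = drugs$id), tibble::as_tibble(m))
}

#' CTD-featurize a table of proteins
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @return A feature table (tibble, `id` + the 147 CTD columns).
#' @export
ctd_table <- function(proteins) {
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    tryCatch(ctd_descriptors(proteins$sequence[i]),
             error = function(e) stop("ctd_table(): entity '", proteins$id[i],
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  m <- do.call(rbind, rows)
  dplyr::bind_cols(tibble::tibble(id = proteins$id), tibble::as_tibble(m))
}

#' Read / write a feature table
#'
#' A feature table is a TSV with a header, an `id` column and a fixed number
#' of numeric columns; it round-trips exactly through the `%.17g` writer.
#'
#' @param path File path.
#' @return Tibble with `id` plus numeric columns (reader); `path` (writer).
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  if (length(body) == 0) {
    out <- tibble::as_tibble(
      stats::setNames(as.list(rep(list(double(0)), length(header))), header))
    out$id <- character(0)
    return(out[, header])
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    stop("read_feature_table(): line ", bad + 1, " has ", nf[bad],
         " fields (expected ", length(header), ")", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
  id_col <- which(header == "id")
  vals <- suppressWarnings(
    matrix(as.double(m[, -id_col, drop = FALSE]), nrow = nrow(m)))
  if (anyNA(vals)) {
    stop("read_feature_table(): non-numeric value in the feature block",
         call. = FALSE)
  }
  out <- tibble::as_tibble(vals, .name_repair = "minimal")
  names(out) <- header[-id_col]
  dplyr::bind_cols(tibble::tibble(id = m[, id_col]), out)
}

#' @rdname read_feature_table
#' @param features Tibble with an `id` column and numeric feature columns.
#' @export
write_feature_table <- function(features, path) {
  stopifnot("id" %in% names(features))
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste(names(features), collapse = "\t"), con)
  if (nrow(features) > 0) {
    num <- as.matrix(features[, setdiff(names(features), "id")])
    body <- apply(num, 1, function(v) paste(sprintf("%.17g", v), collapse = "\t"))
    writeLines(paste(features$id, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Feature-table width (number of feature columns)
#' @param features A feature table tibble.
#' @export
feature_width <- function(features) ncol(features) - 1L

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` (first token of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                   sequence = unname(as.character(ss)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    grp <- cumsum(hdr)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
    tibble::tibble(id = ids, sequence = unname(seqs))
  }
}

#' Write protein sequences as FASTA
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  con <- file(path, "wt"); on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(c(paste0(">", proteins$id[i]),
                 gsub("(.{60})", "\\1\n", proteins$sequence[i])), con)
  }
  invisible(path)
}

#' Read a drug SMILES table (2-column TSV: id, smiles)
#' @param path File path.
#' @return Tibble with columns `id`, `smiles`.
#' @export
read_smiles <- function(path) {
  readr::read_tsv(path, col_names = c("id", "smiles"), col_types = "cc",
                  comment = "#", progress = FALSE)
}
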