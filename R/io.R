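#' Read X-linked case-parent triads from ped/map text files
#'
#' Parses the whitespace-delimited pedigree dialect (six leading columns:
#' family, individual, father, mother, sex 1=male/2=female, phenotype
#' 2=affected; then two allele columns per SNP; missing allele `"0"`) together
#' with a map file (`chrom snp_id [cM] position`). A triad is an affected
#' child plus the two parents named in its pedigree columns. Male X genotypes
#' may be written as homozygous pairs (`"a a"`); a heterozygous male call is a
#' genotyping artifact and is converted to missing with a warning. Families
#' without an affected child (phenotype 2) are rejected with a warning.
#'
#' The variant allele at each SNP is the less frequent allele among all
#' parsed calls (ties broken so the lexicographically first label is the
#' reference).
#'
#' @param ped_path,map_path Paths to the ped and map files.
#' @return A [triad_data()] object with SNPs in map order.
#' @export
read_triads <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- lapply(seq_along(map_lines), function(i) {
    f <- strsplit(trimws(map_lines[i]), "\\s+")[[1]]
    if (!length(f) %in% c(3L, 4L)) {
      abort(sprintf("map line %d: expected 3 or 4 fields, got %d", i, length(f)))
    }
    pos <- suppressWarnings(as.integer(f[length(f)]))
    if (is.na(pos)) abort(sprintf("map line %d: position is not an integer", i))
    list(snp_id = f[2], position = pos)
  })
  snp_ids <- vapply(map, `[[`, character(1), "snp_id")
  if (anyDuplicated(snp_ids)) {
    abort(sprintf("duplicate SNP id in map: %s",
                  paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", ")))
  }
  m <- length(snp_ids)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_ind <- length(ped_lines)
  fam <- iid <- pat <- mat <- character(n_ind)
  sex <- phen <- integer(n_ind)
  a1 <- a2 <- matrix(NA_character_, n_ind, m)
  for (i in seq_len(n_ind)) {
    f <- strsplit(trimws(ped_lines[i]), "\\s+")[[1]]
    if (length(f) != 6L + 2L * m) {
      abort(sprintf("ped line %d: expected %d fields (6 + 2 alleles x %d SNPs), got %d",
                    i, 6L + 2L * m, m, length(f)))
    }
    fam[i] <- f[1]; iid[i] <- f[2]; pat[i] <- f[3]; mat[i] <- f[4]
    sex[i] <- suppressWarnings(as.integer(f[5]))
    phen[i] <- suppressWarnings(as.integer(f[6]))
    al <- f[-(1:6)]
    al[al == "0"] <- NA_character_
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }

  # allele labels per SNP: reference = most frequent call, ties lexicographic
  allele_ref <- allele_var <- character(m)
  for (j in seq_len(m)) {
    calls <- c(a1[, j], a2[, j])
    tt <- sort(table(calls[!is.na(calls)]), decreasing = TRUE)
    if (length(tt) > 2L) {
      abort(sprintf("SNP %s: more than two alleles observed (%s)",
                    snp_ids[j], paste(names(tt), collapse = ", ")))
    }
    if (length(tt) == 0L) { allele_ref[j] <- "A"; allele_var[j] <- NA_character_; next }
    lv <- names(tt)
    if (length(lv) == 2L && tt[1] == tt[2]) lv <- sort(lv)
    allele_ref[j] <- lv[1]
    allele_var[j] <- if (length(lv) == 2L) lv[2] else NA_character_
  }

  key <- paste(fam, iid, sep = "\r")
  children <- which(pat != "0" & mat != "0")
  children <- children[phen[children] == 2L]
  skipped <- setdiff(unique(fam), unique(fam[children]))
  if (length(skipped)) {
    warn(sprintf("%d famil%s without an affected child rejected: %s",
                 length(skipped), if (length(skipped) == 1) "y" else "ies",
                 paste(skipped, collapse = ", ")))
  }
  if (!length(children)) abort("no affected children with both parents found in ped file")

  dose_of <- function(i, j, male) {
    x <- c(a1[i, j], a2[i, j])
    if (any(is.na(x))) return(NA_integer_)
    if (male && x[1] != x[2]) return(-1L) # heterozygous male sentinel
    if (is.na(allele_var[j])) return(0L)
    sum(x == allele_var[j])
  }

  n <- length(children)
  mother <- father <- child <- matrix(NA_integer_, n, m)
  child_sex <- character(n)
  triad_id <- character(n)
  n_het_male <- 0L
  for (k in seq_len(n)) {
    i_c <- children[k]
    if (!sex[i_c] %in% c(1L, 2L)) {
      abort(sprintf("ped family %s, child %s: unknown sex code %s",
                    fam[i_c], iid[i_c], sex[i_c]))
    }
    child_sex[k] <- if (sex[i_c] == 2L) "female" else "male"
    triad_id[k] <- paste0(fam[i_c], ":", iid[i_c])
    i_m <- match(paste(fam[i_c], mat[i_c], sep = "\r"), key)
    i_f <- match(paste(fam[i_c], pat[i_c], sep = "\r"), key)
    male_child <- child_sex[k] == "male"
    for (j in seq_len(m)) {
      if (!is.na(i_m)) {
        mother[k, j] <- max(dose_of(i_m, j, male = FALSE), 0L) # mothers never hit sentinel
      }
      if (!is.na(i_f)) {
        d <- dose_of(i_f, j, male = TRUE)
        if (identical(d, -1L)) { n_het_male <- n_het_male + 1L; d <- NA_integer_ }
        else if (!is.na(d)) d <- min(d, 1L) # "a a" homozygous coding collapses to 1
        father[k, j] <- d
      }
      d <- dose_of(i_c, j, male = male_child)
      if (identical(d, -1L)) { n_het_male <- n_het_male + 1L; d <- NA_integer_ }
      else if (male_child && !is.na(d)) d <- min(d, 1L)
      child[k, j] <- d
    }
  }
  if (n_het_male > 0L) {
    warn(sprintf("%d heterozygous male X call(s) set to missing", n_het_male))
  }
  triad_data(
    snps = tibble(snp_id = snp_ids,
                  position = vapply(map, `[[`, integer(1), "position"),
                  allele_ref = allele_ref, allele_var = allele_var),
    triads = tibble(triad_id = triad_id, child_sex = child_sex),
    mother = mother, father = father, child = child
  )
}

#' Read / write the native long triad TSV format
#'
#' One row per triad per SNP with columns `triad_id`, `snp_id`, `child_sex`,
#' `mother_dose`, `father_dose`, `child_dose`, plus a SNP table
#' (`snp_id`, `position`, `allele_ref`, `allele_var`) in a companion file or
#' supplied directly.
#'
#' @param path Path to the long genotype TSV.
#' @param snps Either a tibble of SNP metadata or the path to a TSV holding it.
#' @return A [triad_data()] object.
#' @export
read_triads_tsv <- function(path, snps) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (is.character(snps)) snps <- readr::read_tsv(snps, show_col_types = FALSE, progress = FALSE)
  snps <- as_tibble(snps)
  triads <- dplyr::distinct(long, .data$triad_id, .data$child_sex)
  n <- nrow(triads); m <- nrow(snps)
  ti <- match(long$triad_id, triads$triad_id)
  si <- match(long$snp_id, snps$snp_id)
  if (anyNA(si)) abort("genotype rows refer to SNPs absent from the SNP table")
  grab <- function(col) {
    mat <- matrix(NA_integer_, n, m)
    mat[cbind(ti, si)] <- as.integer(long[[col]])
    mat
  }
  triad_data(snps = snps, triads = triads,
             mother = grab("mother_dose"), father = grab("father_dose"),
             child = grab("child_dose"))
}

#' @rdname read_triads_tsv
#' @param dataset A `triad_data` object.
#' @param snps_path Optional path for the SNP metadata TSV.
#' @export
write_triads_tsv <- function(dataset, path, snps_path = NULL) {
  readr::write_tsv(as_tibble(dataset), path, progress = FALSE)
  if (!is.null(snps_path)) readr::write_tsv(dataset$snps, snps_path, progress = FALSE)
  invisible(path)
}

#' Write triads in ped/map form
#'
#' Males are written with the homozygous two-allele coding (`"a a"`);
#' missing calls as `"0 0"`. Monomorphic SNPs use a placeholder variant label.
#'
#' @param dataset A `triad_data` object.
#' @param ped_path,map_path Output paths.
#' @export
write_triads_ped <- function(dataset, ped_path, map_path) {
  snps <- dataset$snps
  av <- ifelse(is.na(snps$allele_var), "B", snps$allele_var)
  ar <- snps$allele_ref
  gt_female <- function(d, j) {
    if (is.na(d)) "0 0"
    else paste(c(rep(av[j], d), rep(ar[j], 2 - d)), collapse = " ")
  }
  gt_male <- function(d, j) {
    if (is.na(d)) "0 0" else paste(rep(if (d == 1) av[j] else ar[j], 2), collapse = " ")
  }
  lines <- character(0)
  for (k in seq_len(n_triads(dataset))) {
    fam <- dataset$triads$triad_id[k]
    sexc <- if (dataset$triads$child_sex[k] == "female") 2L else 1L
    male_child <- sexc == 1L
    g_m <- vapply(seq_len(n_snps(dataset)), function(j) gt_female(dataset$mother[k, j], j), character(1))
    g_f <- vapply(seq_len(n_snps(dataset)), function(j) gt_male(dataset$father[k, j], j), character(1))
    g_c <- vapply(seq_len(n_snps(dataset)), function(j) {
      if (male_child) gt_male(dataset$child[k, j], j) else gt_female(dataset$child[k, j], j)
    }, character(1))
    lines <- c(lines,
               paste(fam, "mother", "0", "0", 2L, 1L, paste(g_m, collapse = " ")),
               paste(fam, "father", "0", "0", 1L, 1L, paste(g_f, collapse = " ")),
               paste(fam, "child", "father", "mother", sexc, 2L, paste(g_c, collapse = " ")))
  }
  writeLines(lines, ped_path)
  writeLines(sprintf("X %s 0 %d", snps$snp_id, snps$position), map_path)
  invisible(ped_path)
}
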