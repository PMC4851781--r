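#' Synthetic de-identification instances
#'
#' Generators for datasets and balanced generalization hierarchies so that
#' every part of the package can be exercised without external data. They
#' emulate the shape of typical de-identification workloads: a handful of
#' categorical quasi-identifiers (demographics such as age bands, marital
#' status, sex), balanced interval hierarchies, optionally skewed value
#' frequencies, and a controllable fraction of outlier records — unique
#' attribute combinations that create genuine suppression pressure.
#'
#' @name synthetic-instances
NULL

# run `expr` under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Balanced interval hierarchy over an integer-coded domain
#'
#' Builds a hierarchy for a domain of `domain_size` integer-coded values
#' (`"1" ... "M"`): level `l` groups runs of `branching^l` consecutive
#' values under an interval label `"[lo-hi]"`, up to the first level that
#' covers the whole domain with a single root label. The construction is
#' deterministic.
#'
#' @param domain_size number of base values (>= 1).
#' @param branching grouping factor per level (>= 2).
#' @param attribute attribute name.
#' @return a [hierarchy()]; height is `ceil(log_branching(M)) + 1` (1 for
#'   a singleton domain).
#' @examples
#' synth_hierarchy(8, 2)$height   # 4
#' @export
synth_hierarchy <- function(domain_size, branching = 2L,
                            attribute = "attr") {
  domain_size <- as.integer(domain_size)
  branching <- as.integer(branching)
  if (domain_size < 1L) stop("domain_size must be >= 1")
  if (branching < 2L) stop("branching must be >= 2")
  vals <- as.character(seq_len(domain_size))
  cols <- list(vals)
  width <- branching
  while (width / branching < domain_size && domain_size > 1L) {
    lo <- ((seq_len(domain_size) - 1L) %/% width) * width + 1L
    hi <- pmin(lo + width - 1L, domain_size)
    cols[[length(cols) + 1L]] <- ifelse(lo == hi, as.character(lo),
                                        paste0("[", lo, "-", hi, "]"))
    if (all(lo == 1L)) break
    width <- width * branching
  }
  hierarchy(do.call(cbind, cols), attribute)
}

#' Generate a random de-identification instance
#'
#' Draws `n` records over `length(domains)` integer-coded attributes.
#' Value frequencies are uniform or Zipf-distributed (probability of value
#' `v` proportional to `v^-exponent`, creating realistic class-size skew).
#' A fraction of records is replaced by *outliers*: combinations taken
#' from the rare end of every domain, kept distinct from each other and
#' from all regular records, so that they form singleton equivalence
#' classes at low generalization levels.
#'
#' @param n number of records.
#' @param domains integer vector of per-attribute domain sizes.
#' @param branching per-attribute hierarchy branching factor(s).
#' @param dist `"uniform"` or `"zipf"`.
#' @param zipf_exponent Zipf exponent (default 1).
#' @param outlier_fraction fraction of records drawn from the unique tail;
#'   exactly `floor(outlier_fraction * n)` records.
#' @param seed integer seed; identical seeds give identical instances and
#'   the caller's RNG stream is left untouched.
#' @return list with `data` (validated data frame), `hierarchies`,
#'   `spec` (a [lattice_spec()]) and the generating parameters.
#' @export
synth_instance <- function(n, domains, branching = 2L,
                           dist = c("uniform", "zipf"),
                           zipf_exponent = 1, outlier_fraction = 0,
                           seed = NULL) {
  dist <- match.arg(dist)
  n <- as.integer(n)
  domains <- as.integer(domains)
  m <- length(domains)
  if (m < 1L) stop("at least one attribute is required")
  branching <- rep_len(as.integer(branching), m)
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stop("outlier_fraction must lie in [0, 1]")
  hierarchies <- lapply(seq_len(m), function(i)
    synth_hierarchy(domains[i], branching[i], paste0("attr", i)))
  n_out <- as.integer(floor(outlier_fraction * n))
  cells <- .with_seed(seed, {
    main <- lapply(seq_len(m), function(i) {
      p <- if (dist == "zipf")
        seq_len(domains[i])^(-zipf_exponent)
      else rep(1, domains[i])
      sample.int(domains[i], n, replace = TRUE, prob = p / sum(p))
    })
    mat <- do.call(cbind, main)
    if (n_out > 0L) {
      rows <- (n - n_out + 1L):n        # outliers overwrite the tail rows
      taken <- new.env(parent = emptyenv())
      for (r in seq_len(n - n_out)) assign(paste(mat[r, ], collapse = "."),
                                           TRUE, envir = taken)
      combo_at <- function(code) {      # mixed-radix walk from the rare end
        combo <- integer(m)
        for (i in seq_len(m)) {
          combo[i] <- domains[i] - (code %% domains[i])
          code <- code %/% domains[i]
        }
        combo
      }
      space <- prod(as.numeric(domains))
      placed <- 0L
      code <- 0
      while (placed < n_out && code < space) {
        combo <- combo_at(code)
        code <- code + 1
        key <- paste(combo, collapse = ".")
        if (exists(key, envir = taken, inherits = FALSE)) next
        assign(key, TRUE, envir = taken)
        placed <- placed + 1L
        mat[rows[placed], ] <- combo
      }
      # tiny domains cannot host combinations disjoint from the kept
      # records; keep the outliers at least distinct from each other
      code <- 0
      outs <- new.env(parent = emptyenv())
      while (placed < n_out && code < space) {
        combo <- combo_at(code)
        code <- code + 1
        key <- paste(combo, collapse = ".")
        if (exists(key, envir = outs, inherits = FALSE)) next
        assign(key, TRUE, envir = outs)
        placed <- placed + 1L
        mat[rows[placed], ] <- combo
      }
      if (placed < n_out)
        stop("domain too small to place ", n_out, " distinct outliers")
    }
    mat
  })
  data <- as.data.frame(matrix(as.character(cells), nrow = n),
                        stringsAsFactors = FALSE)
  names(data) <- vapply(hierarchies, function(h) h$attribute, character(1))
  data <- validate_qidata(data, hierarchies)
  list(data = data, hierarchies = hierarchies,
       spec = lattice_spec_for(hierarchies),
       params = list(n = n, domains = domains, branching = branching,
                     dist = dist, zipf_exponent = zipf_exponent,
                     outlier_fraction = outlier_fraction, seed = seed))
}

#' A small age/sex demonstration instance
#'
#' A two-attribute fixture mirroring the classic demographics example: an
#' age-like attribute with a three-level hierarchy (exact age, ten-year
#' interval, `*`) and a sex-like attribute with a two-level hierarchy.
#' The records are constructed so that generalizing age one step while
#' leaving sex untouched — policy `(1, 0)` — leaves exactly one unique
#' record; suppressing it yields a 2-anonymous dataset with a maximal
#' re-identification risk of 50 %.
#'
#' @return list with `data`, `hierarchies` and `facts`, a list of
#'   machine-checkable statements about the instance: `lattice_size` (6),
#'   `policy` (`c(1, 0)`), `suppressed_at_policy` (1) and
#'   `max_risk_after` (0.5).
#' @export
toy_demographics <- function() {
  age <- hierarchy(rbind(
    c("25", "[20-29]", "*"),
    c("27", "[20-29]", "*"),
    c("31", "[30-39]", "*"),
    c("38", "[30-39]", "*"),
    c("45", "[40-49]", "*")), "age")
  sex <- hierarchy(rbind(
    c("male", "*"),
    c("female", "*")), "sex")
  data <- data.frame(
    age = c("25", "27", "31", "38", "45"),
    sex = c("male", "male", "female", "female", "male"),
    stringsAsFactors = FALSE)
  list(data = validate_qidata(data, list(age, sex)),
       hierarchies = list(age, sex),
       facts = list(lattice_size = 6, policy = c(1L, 0L),
                    suppressed_at_policy = 1L, max_risk_after = 0.5))
}

#' Write a synthetic instance bundle to disk
#'
#' Writes the dataset CSV, one hierarchy file per attribute and a JSON
#' manifest recording the generating parameters, so that an instance can
#' be re-generated and verified byte for byte.
#'
#' @param inst a [synth_instance()] (or [toy_demographics()]-shaped) list.
#' @param dir output directory (created if missing).
#' @param name basename for the files.
#' @return invisibly, the paths written.
#' @export
write_instance <- function(inst, dir, name = "instance") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data_path <- file.path(dir, paste0(name, ".csv"))
  write_qidata(inst$data, data_path)
  hpaths <- vapply(inst$hierarchies, function(h) {
    p <- file.path(dir, paste0(name, "_", h$attribute, ".hierarchy.csv"))
    write_hierarchy(h, p)
    p
  }, character(1))
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(
    list(name = name, params = inst$params,
         files = c(data_path, hpaths),
         md5 = as.list(tools::md5sum(c(data_path, hpaths)))),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(data = data_path, hpaths, manifest = manifest))
}
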