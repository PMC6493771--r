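#' Gene-based enrichment p-value of a minimal network
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k` deregulated genes in a network of `K` genes, when `n` of the `N`
#' genes of the whole model are deregulated.  Computed by direct log-space
#' summation of the hypergeometric density, with no normal approximation.
#'
#' @param k deregulated genes in the network.
#' @param K total genes in the network.
#' @param n deregulated genes in the model.
#' @param N total genes in the model.
#' @return the p-value in `[0, 1]`.
#' @export
gene_pvalue <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
      k > min(K, n)) {
    stop("invalid hypergeometric arguments: k=", k, " K=", K,
         " n=", n, " N=", N)
  }
  i <- seq.int(k, min(K, n))
  p <- sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
  min(max(p, 0), 1)
}

check_censuses <- function(census, min_census) {
  census <- as.numeric(census); min_census <- as.numeric(min_census)
  if (length(census) != 4L || census[1] != sum(census[2:4])) {
    stop("model census must be (R, R_up, R_down, R_no) with R = R_up + R_down + R_no")
  }
  if (length(min_census) != 3L || min_census[2] + min_census[3] > min_census[1]) {
    stop("network census must be (T, T_up, T_down) with T_up + T_down <= T")
  }
  if (min_census[1] > census[1]) stop("network larger than model (T > R)")
  list(census = census, min_census = min_census)
}

#' Upregulation p-value of a minimal network (multivariate hypergeometric)
#'
#' Probability that a uniformly drawn set of `T` reactions from a model
#' with `R_up` upregulated, `R_down` downregulated and `R_no` unregulated
#' reactions contains at least `T_up` upregulated and at most `T_down`
#' downregulated ones:
#' \deqn{p = \sum_{i = T_{up}}^{\min(R_{up}, T)} \sum_{j=0}^{T_{down}}
#'   \frac{\binom{R_{up}}{i}\binom{R_{down}}{j}\binom{R_{no}}{T-i-j}}
#'        {\binom{R}{T}}, \qquad i + j \le T.}
#' Small values flag networks with an elevated number of upregulated
#' reactions and as few downregulated ones as possible.
#'
#' @param census model census `(R, R_up, R_down, R_no)`.
#' @param min_census network census `(T, T_up, T_down)`.
#' @return the p-value in `[0, 1]`.
#' @export
up_pvalue <- function(census, min_census) {
  cc <- check_censuses(census, min_census)
  mh_tail(R_a = cc$census[2], R_b = cc$census[3], R_no = cc$census[4],
          T_tot = cc$min_census[1], T_a = cc$min_census[2],
          T_b = cc$min_census[3])
}

#' Downregulation p-value of a minimal network
#'
#' Mirror of [up_pvalue()] with the roles of up- and downregulated
#' reactions exchanged.
#'
#' @inheritParams up_pvalue
#' @return the p-value in `[0, 1]`.
#' @export
down_pvalue <- function(census, min_census) {
  cc <- check_censuses(census, min_census)
  mh_tail(R_a = cc$census[3], R_b = cc$census[2], R_no = cc$census[4],
          T_tot = cc$min_census[1], T_a = cc$min_census[3],
          T_b = cc$min_census[2])
}

# joint tail over (i >= T_a, j <= T_b, i + j <= T) of the multivariate
# hypergeometric law with categories (R_a, R_b, R_no)
mh_tail <- function(R_a, R_b, R_no, T_tot, T_a, T_b) {
  R <- R_a + R_b + R_no
  denom <- lchoose(R, T_tot)
  i_max <- min(R_a, T_tot)
  if (T_a > i_max) return(0)
  total <- 0
  for (i in seq.int(T_a, i_max)) {
    j_max <- min(T_b, R_b, T_tot - i)
    if (j_max < 0) next
    for (j in seq.int(0, j_max)) {
      rest <- T_tot - i - j
      if (rest > R_no) next
      total <- total + exp(lchoose(R_a, i) + lchoose(R_b, j) +
                             lchoose(R_no, rest) - denom)
    }
  }
  min(max(total, 0), 1)
}

#' Census of a minimal network under a regulation assignment
#'
#' Counts the network's reactions by regulation state and its genes by
#' deregulation status.
#'
#' @param network a `minea_min_network` (or character vector of parent ids).
#' @param model the `minea_model`.
#' @param regulation a `minea_regulation`.
#' @return list with `T`, `T_up`, `T_down`, `T_no` (reaction counts,
#'   `T = T_up + T_down + T_no`), `K` (genes in the network) and `k`
#'   (deregulated genes in the network).
#' @export
min_network_census <- function(network, model, regulation) {
  if (inherits(network, "minea_min_network")) {
    network <- network$active_reactions
  }
  stopifnot(inherits(regulation, "minea_regulation"))
  states <- regulation$reaction_states[network]
  if (anyNA(states)) {
    stop("network reactions missing from the regulation assignment: ",
         paste(network[is.na(states)], collapse = ", "))
  }
  rxn <- model$reactions
  member_ids <- rxn$id[rxn$parent_id %in% network]
  genes <- unique(unlist(lapply(member_ids, genes_of, model = model),
                         use.names = FALSE))
  k <- length(intersect(genes, names(regulation$gene_calls)))
  list(T = length(states),
       T_up = sum(states == "up"),
       T_down = sum(states == "down"),
       T_no = sum(states == "unregulated"),
       K = length(genes), k = k)
}

#' Deregulated percentage
#'
#' Fraction of a network's genes that are deregulated, `k / K`; the
#' analogous reaction-level fractions `T_up / T` (UPR) and `T_down / T`
#' (DnRP) are reported by [build_report()].
#'
#' @param k deregulated members; @param K total members.
#' @return `k / K`, or `NA` when `K` is 0 (undefined).
#' @export
drp <- function(k, K) {
  stopifnot(k >= 0, K >= 0, k <= K)
  if (K == 0) return(NA_real_)
  k / K
}

#' Alternative minimal network frequency (AMiNF)
#'
#' Fraction of a task's alternative networks whose selected p-value is
#' below `alpha`: 1 when all alternatives are significantly deregulated,
#' 0 when none is.
#'
#' @param pvalues numeric vector of per-network p-values (one mode).
#' @param alpha significance threshold; conventional defaults are 0.05 for
#'   the gene-based mode and 0.005 for the reaction-based modes.
#' @return fraction in `[0, 1]`.
#' @export
aminf <- function(pvalues, alpha) {
  if (length(pvalues) == 0L) stop("no alternatives: AMiNF undefined")
  mean(pvalues < alpha)
}

#' Enrichment report over tasks, alternatives and condition pairs
#'
#' For every alternative network of every task and every regulation
#' assignment, computes the gene-based p-value, the up-/down-regulation
#' p-values, the deregulated fractions, and significance labels; aggregates
#' per-task AMiNF in the three modes; and counts deregulated HFRs per task.
#' Benjamini-Hochberg adjusted columns are emitted for reference but never
#' drive AMiNF, which uses the raw thresholds.
#'
#' @param alt_sets list of `minea_altset` objects (one per task).
#' @param model the `minea_model` the enumerations were computed on.
#' @param regulations list of `minea_regulation` objects (one per
#'   condition pair).
#' @param alpha_gene threshold for the gene-based mode (default 0.05).
#' @param alpha_rxn threshold for the reaction-based modes (default 0.005).
#' @return list of data frames: `networks` (per network x condition),
#'   `aminf` (per task x condition x mode), `hfr_regulation` (per task x
#'   condition counts of up-/down-regulated HFRs).
#' @export
build_report <- function(alt_sets, model, regulations,
                         alpha_gene = 0.05, alpha_rxn = 0.005) {
  stopifnot(length(alt_sets) > 0L, length(regulations) > 0L)
  if (inherits(regulations, "minea_regulation")) {
    regulations <- list(regulations)
  }
  N <- length(model$genes)
  rows <- list(); aminf_rows <- list(); hfr_rows <- list()
  for (reg in regulations) {
    n_dereg <- length(reg$gene_calls)
    for (aset in alt_sets) {
      p_gene <- p_up <- p_down <- numeric(length(aset$networks))
      for (w in seq_along(aset$networks)) {
        net <- aset$networks[[w]]
        cen <- min_network_census(net, model, reg)
        p_gene[w] <- gene_pvalue(cen$k, cen$K, n_dereg, N)
        mc <- c(cen$T, cen$T_up, cen$T_down)
        p_up[w] <- up_pvalue(reg$census, mc)
        p_down[w] <- down_pvalue(reg$census, mc)
        label <- "none"
        if (p_up[w] < alpha_rxn && p_down[w] < alpha_rxn) {
          label <- if (p_up[w] < p_down[w]) "up"
                   else if (p_down[w] < p_up[w]) "down" else "both"
        } else if (p_up[w] < alpha_rxn) label <- "up"
        else if (p_down[w] < alpha_rxn) label <- "down"
        rows[[length(rows) + 1L]] <- data.frame(
          condition = reg$condition, task = aset$task$name, network = w,
          size = net$size, K = cen$K, k = cen$k,
          T_up = cen$T_up, T_down = cen$T_down,
          p_gene = p_gene[w], p_up = p_up[w], p_down = p_down[w],
          drp = drp(cen$k, cen$K),
          urp = drp(cen$T_up, cen$T), dnrp = drp(cen$T_down, cen$T),
          significant_gene = p_gene[w] < alpha_gene,
          regulation_label = label, stringsAsFactors = FALSE)
      }
      for (mode in c("gene", "up", "down")) {
        pv <- switch(mode, gene = p_gene, up = p_up, down = p_down)
        alpha <- if (mode == "gene") alpha_gene else alpha_rxn
        aminf_rows[[length(aminf_rows) + 1L]] <- data.frame(
          condition = reg$condition, task = aset$task$name,
          phenotype = aset$task$phenotype, mode = mode, alpha = alpha,
          n_alternatives = length(pv), aminf = aminf(pv, alpha),
          stringsAsFactors = FALSE)
      }
      hstates <- reg$reaction_states[aset$hfrs]
      hfr_rows[[length(hfr_rows) + 1L]] <- data.frame(
        condition = reg$condition, task = aset$task$name,
        phenotype = aset$task$phenotype, n_hfrs = length(aset$hfrs),
        hfr_up = sum(hstates == "up", na.rm = TRUE),
        hfr_down = sum(hstates == "down", na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  networks <- do.call(rbind, rows)
  networks$p_gene_bh <- stats::p.adjust(networks$p_gene, method = "BH")
  networks$p_up_bh <- stats::p.adjust(networks$p_up, method = "BH")
  networks$p_down_bh <- stats::p.adjust(networks$p_down, method = "BH")
  list(networks = networks,
       aminf = do.call(rbind, aminf_rows),
       hfr_regulation = do.call(rbind, hfr_rows))
}
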