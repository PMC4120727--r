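#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Status codes for a (possibly failed) iHH integration.
// 0 = ok, 1 = edge (EHH never decayed below cutoff before chromosome end),
// 2 = gap (adjacent-SNP physical gap exceeded the limit).
static const int ST_OK = 0, ST_EDGE = 1, ST_GAP = 2;

// Extended haplotype homozygosity of a group partition:
// sum over groups of C(n_g,2) / C(n,2).
static double ehh_from_counts(const std::vector<int>& cnt, int n) {
  double num = 0.0;
  for (size_t g = 0; g < cnt.size(); ++g)
    num += 0.5 * cnt[g] * (cnt[g] - 1.0);
  return num / (0.5 * n * (n - 1.0));
}

// Refine the group labels in grp (values in [0, ngrp)) by the alleles of
// SNP j restricted to rows `rows` of H. Returns the new group count.
static int refine(const IntegerMatrix& H, const std::vector<int>& rows,
                  int j, std::vector<int>& grp, int ngrp,
                  std::vector<int>& remap, std::vector<int>& cnt) {
  remap.assign(2 * ngrp, -1);
  int next = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    int key = 2 * grp[i] + H(rows[i], j);
    if (remap[key] < 0) remap[key] = next++;
    grp[i] = remap[key];
  }
  cnt.assign(next, 0);
  for (size_t i = 0; i < rows.size(); ++i) cnt[grp[i]]++;
  return next;
}

// Drop haplotypes that have become singletons: they contribute nothing to
// EHH from here outward (a lone haplotype can never rejoin a group).
static void drop_singletons(std::vector<int>& rows, std::vector<int>& grp,
                            const std::vector<int>& cnt) {
  size_t k = 0;
  for (size_t i = 0; i < rows.size(); ++i) {
    if (cnt[grp[i]] >= 2) { rows[k] = rows[i]; grp[k] = grp[i]; ++k; }
  }
  rows.resize(k); grp.resize(k);
}

// One-sided iHH for an allele-class carrier set: EHH starts at 1 at the
// core and the trapezoid through the first below-cutoff SNP is included.
static double ihh_side_class(const IntegerMatrix& H,
                             const std::vector<int>& rows0, int core, int dir,
                             const NumericVector& gpos,
                             const NumericVector& pos,
                             double cutoff, double max_gap_bp, int* status) {
  int n = rows0.size(), nsnp = H.ncol();
  std::vector<int> rows(rows0), grp(n, 0), remap, cnt;
  int ngrp = 1;
  double area = 0.0, prev_ehh = 1.0, prev_g = gpos[core], prev_p = pos[core];
  for (int j = core + dir; j >= 0 && j < nsnp; j += dir) {
    if (std::abs(pos[j] - prev_p) > max_gap_bp) { *status = ST_GAP; return NA_REAL; }
    ngrp = refine(H, rows, j, grp, ngrp, remap, cnt);
    double e = ehh_from_counts(cnt, n);
    area += 0.5 * (prev_ehh + e) * std::abs(gpos[j] - prev_g);
    if (e < cutoff) { *status = ST_OK; return area; }
    drop_singletons(rows, grp, cnt);
    prev_ehh = e; prev_g = gpos[j]; prev_p = pos[j];
  }
  *status = ST_EDGE;   // ran off the chromosome end, incl. no flanking SNP
  return NA_REAL;
}

// [[Rcpp::export]]
List ihs_scan_cpp(IntegerMatrix H, NumericVector gpos, NumericVector pos,
                  IntegerVector derived_allele, double cutoff,
                  double max_gap_bp, int min_carriers,
                  double min_daf, double max_daf) {
  int nsnp = H.ncol(), nhap = H.nrow();
  NumericVector daf(nsnp, NA_REAL), ihh_a(nsnp, NA_REAL), ihh_d(nsnp, NA_REAL);
  IntegerVector skip(nsnp, 0);  // 0 ok, 3 no_ancestral, 4 daf, 5 carriers, 1 edge, 2 gap
  for (int s = 0; s < nsnp; ++s) {
    if (derived_allele[s] == NA_INTEGER || derived_allele[s] < 0) { skip[s] = 3; continue; }
    int d = derived_allele[s];
    std::vector<int> der, anc;
    for (int i = 0; i < nhap; ++i)
      (H(i, s) == d ? der : anc).push_back(i);
    double f = (double)der.size() / nhap;
    daf[s] = f;
    if (f < min_daf || f > max_daf) { skip[s] = 4; continue; }
    if ((int)der.size() < min_carriers || (int)anc.size() < min_carriers) {
      skip[s] = 5; continue;
    }
    int st = ST_OK, worst = ST_OK;
    double a_up = ihh_side_class(H, anc, s, -1, gpos, pos, cutoff, max_gap_bp, &st);
    worst = std::max(worst, st);
    double a_dn = ihh_side_class(H, anc, s, +1, gpos, pos, cutoff, max_gap_bp, &st);
    worst = std::max(worst, st);
    double d_up = ihh_side_class(H, der, s, -1, gpos, pos, cutoff, max_gap_bp, &st);
    worst = std::max(worst, st);
    double d_dn = ihh_side_class(H, der, s, +1, gpos, pos, cutoff, max_gap_bp, &st);
    worst = std::max(worst, st);
    if (worst != ST_OK) { skip[s] = (worst == ST_GAP) ? 2 : 1; continue; }
    ihh_a[s] = a_up + a_dn;
    ihh_d[s] = d_up + d_dn;
  }
  return List::create(_["daf"] = daf, _["ihh_a"] = ihh_a, _["ihh_d"] = ihh_d,
                      _["skip"] = skip);
}

// One-sided XP-EHH integration: walk outward refining the pooled panel and
// the two population panels in lockstep. The pooled EHH (core SNP included
// in the haplotype string) sets a common truncation boundary: the trapezoid
// through the first SNP where pooled EHH < cutoff is included for all three
// curves, then integration stops.
static bool xp_side(const IntegerMatrix& H, std::vector<int> rows1,
                    std::vector<int> rows2, int core, int dir,
                    const NumericVector& gpos, const NumericVector& pos,
                    double cutoff, double max_gap_bp,
                    double* area1, double* area2, int* status) {
  int nsnp = H.ncol();
  std::vector<int> pooled(rows1); pooled.insert(pooled.end(), rows2.begin(), rows2.end());
  int np = pooled.size(), n1 = rows1.size(), n2 = rows2.size();
  std::vector<int> gp(np, 0), g1(n1, 0), g2(n2, 0), remap, cnt;
  int ngp = 1, ng1 = 1, ng2 = 1;
  // core SNP itself: groups split by the core allele
  ngp = refine(H, pooled, core, gp, ngp, remap, cnt);
  double ep = ehh_from_counts(cnt, np);
  ng1 = refine(H, rows1, core, g1, ng1, remap, cnt);
  double e1 = ehh_from_counts(cnt, n1);
  ng2 = refine(H, rows2, core, g2, ng2, remap, cnt);
  double e2 = ehh_from_counts(cnt, n2);
  *area1 = 0.0; *area2 = 0.0;
  double prev_g = gpos[core], prev_p = pos[core];
  if (ep < cutoff) { *status = ST_OK; return true; }  // already below at core
  for (int j = core + dir; j >= 0 && j < nsnp; j += dir) {
    if (std::abs(pos[j] - prev_p) > max_gap_bp) { *status = ST_GAP; return false; }
    ngp = refine(H, pooled, j, gp, ngp, remap, cnt);
    double ep_j = ehh_from_counts(cnt, np);
    drop_singletons(pooled, gp, cnt);
    ng1 = refine(H, rows1, j, g1, ng1, remap, cnt);
    double e1_j = ehh_from_counts(cnt, n1);
    drop_singletons(rows1, g1, cnt);
    ng2 = refine(H, rows2, j, g2, ng2, remap, cnt);
    double e2_j = ehh_from_counts(cnt, n2);
    drop_singletons(rows2, g2, cnt);
    double w = std::abs(gpos[j] - prev_g);
    *area1 += 0.5 * (e1 + e1_j) * w;
    *area2 += 0.5 * (e2 + e2_j) * w;
    if (ep_j < cutoff) { *status = ST_OK; return true; }
    ep = ep_j; e1 = e1_j; e2 = e2_j; prev_g = gpos[j]; prev_p = pos[j];
  }
  *status = ST_EDGE;
  return false;
}

// [[Rcpp::export]]
List xpehh_scan_cpp(IntegerMatrix H, IntegerVector is_pop2,
                    NumericVector gpos, NumericVector pos,
                    double cutoff, double max_gap_bp, int min_carriers) {
  int nsnp = H.ncol(), nhap = H.nrow();
  std::vector<int> rows1, rows2;
  for (int i = 0; i < nhap; ++i) (is_pop2[i] ? rows2 : rows1).push_back(i);
  if ((int)rows1.size() < min_carriers || (int)rows2.size() < min_carriers)
    stop("each panel needs at least %d haplotypes", min_carriers);
  NumericVector ihh1(nsnp, NA_REAL), ihh2(nsnp, NA_REAL);
  IntegerVector skip(nsnp, 0);
  for (int s = 0; s < nsnp; ++s) {
    double u1, u2, d1, d2;
    int st = ST_OK, worst = ST_OK;
    if (!xp_side(H, rows1, rows2, s, -1, gpos, pos, cutoff, max_gap_bp, &u1, &u2, &st))
      worst = std::max(worst, st);
    if (!xp_side(H, rows1, rows2, s, +1, gpos, pos, cutoff, max_gap_bp, &d1, &d2, &st))
      worst = std::max(worst, st);
    if (worst != ST_OK) { skip[s] = (worst == ST_GAP) ? 2 : 1; continue; }
    ihh1[s] = u1 + d1;
    ihh2[s] = u2 + d2;
  }
  return List::create(_["ihh_pop1"] = ihh1, _["ihh_pop2"] = ihh2,
                      _["skip"] = skip);
}

// [[Rcpp::export]]
double ehh_at_cpp(IntegerMatrix H, IntegerVector carriers, int core, int target) {
  std::vector<int> rows(carriers.begin(), carriers.end());  // 0-based
  int n = rows.size();
  if (n < 2) stop("need at least 2 carriers");
  int lo = std::min(core, target), hi = std::max(core, target);
  std::vector<int> grp(n, 0), remap, cnt;
  int ngrp = 1;
  cnt.assign(1, n);
  for (int j = lo; j <= hi; ++j)
    ngrp = refine(H, rows, j, grp, ngrp, remap, cnt);
  return ehh_from_counts(cnt, n);
}
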