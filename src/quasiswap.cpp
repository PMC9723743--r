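#include <Rcpp.h>
using namespace Rcpp;

// Unit-transfer mixing on a non-negative integer block. A trial picks two
// distinct rows and columns and transfers one unit along a diagonal of the
// 2x2 submatrix ([[a,b],[c,d]] -> [[a-1,b+1],[c+1,d-1]] or the reverse),
// accepting only moves that keep all four entries non-negative and leave
// the number of zero entries in the submatrix unchanged. Row totals,
// column totals and fill are all invariant. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix quasiswap_chain(IntegerMatrix m, double n_trials) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix x = clone(m);
  if (nr < 2 || nc < 2) return x;
  for (double t = 0; t < n_trials; t++) {
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    int dir = (unif_rand() < 0.5) ? 1 : -1;
    int na = a - dir, nb = b + dir, ncc = c + dir, nd = d - dir;
    if (na < 0 || nb < 0 || ncc < 0 || nd < 0) continue;
    int z0 = (a == 0) + (b == 0) + (c == 0) + (d == 0);
    int z1 = (na == 0) + (nb == 0) + (ncc == 0) + (nd == 0);
    if (z0 != z1) continue;
    x(r1, c1) = na;
    x(r1, c2) = nb;
    x(r2, c1) = ncc;
    x(r2, c2) = nd;
  }
  return x;
}

// Drive the number of non-zero cells of a margin-fixed random table to
// `target_nonzero` by random 2x2 diagonal transfers. A trial draws a
// submatrix and a direction, picks a transfer amount up to the available
// units, and accepts it when it moves the fill toward the target (or is
// fill-neutral, which keeps the walk mixing). Margins are invariant under
// every transfer. Returns the matrix; stops with an error if the target
// fill is not reached within `max_trials` (margins incompatible or
// pathological stall).
// [[Rcpp::export]]
IntegerMatrix quasiswap_fill(IntegerMatrix m, int target_nonzero,
                             double max_trials) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix x = clone(m);
  int nz = 0;
  for (int i = 0; i < nr * nc; i++) nz += (x[i] > 0);
  if (nr < 2 || nc < 2) {
    if (nz != target_nonzero) stop("degenerate block cannot reach target fill");
    return x;
  }
  double t = 0;
  while (nz != target_nonzero) {
    if (t++ >= max_trials) stop("quasiswap fill adjustment did not converge");
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    int a = x(r1, c1), b = x(r1, c2), c = x(r2, c1), d = x(r2, c2);
    // direction 1 moves units off the (a, d) diagonal onto (b, c)
    int dir = (unif_rand() < 0.5) ? 1 : -1;
    int avail = (dir == 1) ? (a < d ? a : d) : (b < c ? b : c);
    if (avail == 0) continue;
    // full transfers create zeros fast; partial transfers keep mixing
    int amt = (unif_rand() < 0.5) ? avail : 1 + (int)(unif_rand() * avail);
    int na = a - dir * amt, nb = b + dir * amt;
    int ncc = c + dir * amt, nd = d - dir * amt;
    int dnz = (na > 0) + (nb > 0) + (ncc > 0) + (nd > 0) -
              ((a > 0) + (b > 0) + (c > 0) + (d > 0));
    // accept any move that does not worsen the distance to the target
    // fill; equal-distance moves (including overshoot) keep the walk
    // from stalling in states with no exact-step move available
    int dist0 = nz - target_nonzero;
    if (dist0 < 0) dist0 = -dist0;
    int dist1 = nz + dnz - target_nonzero;
    if (dist1 < 0) dist1 = -dist1;
    if (dist1 > dist0) continue;
    x(r1, c1) = na;
    x(r1, c2) = nb;
    x(r2, c1) = ncc;
    x(r2, c2) = nd;
    nz += dnz;
  }
  return x;
}
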