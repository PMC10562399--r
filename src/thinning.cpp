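#include <Rcpp.h>
using namespace Rcpp;

// Directional border-peeling thinning (Zhang-Suen family).
//
// Each iteration runs four subpasses (N, S, E, W). A subpass first snapshots
// the current border set -- foreground pixels whose neighbour on the pass
// direction is background -- so it peels exactly one boundary layer; the
// snapshot prevents a deletion from exposing the next pixel in scan order
// within the same subpass. Candidates are then deleted sequentially when
//   * they still have >= 2 foreground 8-neighbours (endpoints and isolated
//     pixels are kept, so line ends do not erode and components never
//     vanish), and
//   * their crossing number A(P) -- 0->1 transitions walking the 8-neighbour
//     ring -- equals 1 on the CURRENT image, i.e. the remaining neighbours
//     form a single connected arc, so removing P cannot split a component.
// Sequential deletion makes topology preservation exact; passes repeat until
// a fixed point, so the result is idempotent by construction. The image
// border is background.

static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static inline bool deletable(const LogicalMatrix& img, int r, int c,
                             int nr, int nc) {
  int nb[8], B = 0;
  for (int k = 0; k < 8; ++k) {
    int rr = r + DR[k], cc = c + DC[k];
    nb[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc)) ? 1 : 0;
    B += nb[k];
  }
  if (B < 2) return false;
  int runs = 0;
  for (int k = 0; k < 8; ++k)
    if (!nb[k] && nb[(k + 1) % 8]) ++runs;
  return runs == 1;
}

// After local thinning converges, fully-true 2x2 blocks can remain where
// every block pixel has crossing number >= 2 (a local cut). Many of those
// pixels are still globally redundant: their neighbour arcs reconnect
// through the rest of the skeleton. This checks, by BFS on the current
// image with the pixel removed, whether all its foreground neighbours stay
// mutually connected; if so the deletion is topology-safe.
static bool globally_redundant(const LogicalMatrix& img, int r, int c,
                               int nr, int nc, std::vector<char>& seen) {
  std::vector<int> nbr;
  for (int k = 0; k < 8; ++k) {
    int rr = r + DR[k], cc = c + DC[k];
    if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc))
      nbr.push_back(cc * nr + rr);
  }
  if (nbr.size() < 2) return false;
  std::fill(seen.begin(), seen.end(), 0);
  seen[c * nr + r] = 2;                  // the removed pixel is impassable
  std::vector<int> queue;
  queue.push_back(nbr[0]);
  seen[nbr[0]] = 1;
  size_t head = 0;
  while (head < queue.size()) {
    int idx = queue[head++];
    int qr = idx % nr, qc = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = qr + DR[k], cc = qc + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = cc * nr + rr;
      if (seen[j] || !img(rr, cc)) continue;
      seen[j] = 1;
      queue.push_back(j);
    }
  }
  for (size_t t = 1; t < nbr.size(); ++t)
    if (seen[nbr[t]] != 1) return false;
  return true;
}

// [[Rcpp::export]]
LogicalMatrix thin_mask_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img = clone(mask);
  const int passdir[4] = {0, 4, 2, 6};  // N, S, E, W
  std::vector<int> cand_r, cand_c;
  std::vector<char> seen(static_cast<size_t>(nr) * nc);
  bool outer_changed = true;
  while (outer_changed) {
    outer_changed = false;
    bool changed = true;
    while (changed) {
      changed = false;
      for (int p = 0; p < 4; ++p) {
        cand_r.clear(); cand_c.clear();
        int dr = DR[passdir[p]], dc = DC[passdir[p]];
        for (int c = 0; c < nc; ++c)
          for (int r = 0; r < nr; ++r) {
            if (!img(r, c)) continue;
            int rr = r + dr, cc = c + dc;
            bool dir_bg = !(rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
                            img(rr, cc));
            if (dir_bg) { cand_r.push_back(r); cand_c.push_back(c); }
          }
        for (size_t i = 0; i < cand_r.size(); ++i) {
          int r = cand_r[i], c = cand_c[i];
          if (img(r, c) && deletable(img, r, c, nr, nc)) {
            img(r, c) = false;
            changed = true;
            outer_changed = true;
          }
        }
      }
    }
    // resolve residual 2x2 blocks with the global redundancy check
    for (int c = 0; c + 1 < nc; ++c)
      for (int r = 0; r + 1 < nr; ++r) {
        if (!(img(r, c) && img(r + 1, c) && img(r, c + 1) &&
              img(r + 1, c + 1)))
          continue;
        const int br[4] = {r, r + 1, r, r + 1};
        const int bc[4] = {c, c, c + 1, c + 1};
        for (int k = 0; k < 4; ++k) {
          if (deletable(img, br[k], bc[k], nr, nc) ||
              globally_redundant(img, br[k], bc[k], nr, nc, seen)) {
            img(br[k], bc[k]) = false;
            outer_changed = true;
            break;
          }
        }
      }
  }
  return img;
}
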