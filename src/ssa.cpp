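#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method Gillespie simulation of the mean-field two-codon network.
// Five reaction channels: charging of each tRNA species, ribosome binding,
// and elongation from each codon class. An elongation event terminates with
// probability 1/L (geometric transcript-length approximation), otherwise the
// ribosome re-lands on an optimal codon with probability f_op. All random
// draws come from R's RNG, so trajectories are reproducible via set.seed().
//
// Records the state on the regular grid 0, dt, 2dt, ..., t_max (value held
// over [t, t_next) is recorded at every grid time it spans).
// [[Rcpp::export]]
NumericMatrix ssa_meanfield_cpp(IntegerVector init, double k_charge,
                                double k_speed, double k_bind, double f_op,
                                int L, int N, double t_max,
                                double record_interval) {
  double Tc1 = init[0], Tc2 = init[1], Tu1 = init[2], Tu2 = init[3];
  double Rf = init[4], Rb1 = init[5], Rb2 = init[6];
  double protein = 0.0;
  const double inv_L = 1.0 / (double)L;
  const int n_rec = (int)std::floor(t_max / record_interval + 1e-9) + 1;
  NumericMatrix rec(n_rec, 9);
  int irec = 0;
  double next_rec = 0.0, t = 0.0;
  RNGScope scope;
  for (;;) {
    const double a1 = k_charge * Tu1, a2 = k_charge * Tu2,
                 a3 = k_bind * (double)N * Rf,
                 a4 = k_speed * Rb1 * Tc1, a5 = k_speed * Rb2 * Tc2;
    const double a0 = a1 + a2 + a3 + a4 + a5;
    const double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    while (irec < n_rec && next_rec <= t_next) {
      rec(irec, 0) = next_rec;
      rec(irec, 1) = Tc1; rec(irec, 2) = Tc2;
      rec(irec, 3) = Tu1; rec(irec, 4) = Tu2;
      rec(irec, 5) = Rf;  rec(irec, 6) = Rb1; rec(irec, 7) = Rb2;
      rec(irec, 8) = protein;
      ++irec;
      next_rec = (double)irec * record_interval;
    }
    if (irec >= n_rec || !(a0 > 0.0)) break;
    t = t_next;
    const double u = unif_rand() * a0;
    if (u < a1) {
      Tu1 -= 1; Tc1 += 1;
    } else if (u < a1 + a2) {
      Tu2 -= 1; Tc2 += 1;
    } else if (u < a1 + a2 + a3) {
      Rf -= 1;
      if (unif_rand() < f_op) Rb1 += 1; else Rb2 += 1;
    } else if (u < a1 + a2 + a3 + a4) {
      Tc1 -= 1; Tu1 += 1;
      if (unif_rand() < inv_L) {
        Rb1 -= 1; Rf += 1; protein += 1;
      } else if (unif_rand() >= f_op) {
        Rb1 -= 1; Rb2 += 1;
      }
    } else {
      Tc2 -= 1; Tu2 += 1;
      if (unif_rand() < inv_L) {
        Rb2 -= 1; Rf += 1; protein += 1;
      } else if (unif_rand() < f_op) {
        Rb2 -= 1; Rb1 += 1;
      }
    }
  }
  colnames(rec) = CharacterVector::create("time", "T_c1", "T_c2", "T_u1",
                                          "T_u2", "R_f", "R_b1", "R_b2",
                                          "protein");
  return rec;
}

// Codon-resolved Gillespie simulation: every ribosome carries a transcript
// index and codon position; its elongation propensity is k_speed * T_c of
// the codon class under it, so ribosomes on the same class are exchangeable
// and can be sampled uniformly within class. Termination is positional
// (stepping past codon L). Optional steric exclusion with a given footprint
// (codons) is implemented by thinning: a blocked ribosome or blocked binding
// site yields a null event, which keeps the direct method exact.
//
// seqs: N x L integer matrix of codon classes (1 = optimal, 2 = non-optimal).
// init: (Tc1, Tc2, Tu1, Tu2, Rf); all ribosomes start free.
// [[Rcpp::export]]
NumericMatrix ssa_codon_cpp(IntegerMatrix seqs, IntegerVector init,
                            double k_charge, double k_speed, double k_bind,
                            int footprint, double t_max,
                            double record_interval) {
  const int N = seqs.nrow(), L = seqs.ncol();
  double Tc1 = init[0], Tc2 = init[1], Tu1 = init[2], Tu2 = init[3];
  double Rf = init[4];
  double protein = 0.0;

  // ribosome storage indexed by id; ids recycled through a free list
  std::vector<int> rib_tr, rib_pos, rib_cls, rib_slot;
  std::vector<int> free_ids;
  std::vector<int> cls_members[2]; // ribosome ids currently on class 1 / 2
  std::vector<unsigned char> occ;  // head-position occupancy, for exclusion
  if (footprint > 0) occ.assign((size_t)N * L, 0);

  const int n_rec = (int)std::floor(t_max / record_interval + 1e-9) + 1;
  NumericMatrix rec(n_rec, 9);
  int irec = 0;
  double next_rec = 0.0, t = 0.0;

  auto add_rib = [&](int tr, int pos) {
    int id;
    if (!free_ids.empty()) {
      id = free_ids.back(); free_ids.pop_back();
    } else {
      id = (int)rib_tr.size();
      rib_tr.push_back(0); rib_pos.push_back(0);
      rib_cls.push_back(0); rib_slot.push_back(0);
    }
    int cls = seqs(tr, pos - 1); // class of codon under the ribosome
    rib_tr[id] = tr; rib_pos[id] = pos; rib_cls[id] = cls;
    rib_slot[id] = (int)cls_members[cls - 1].size();
    cls_members[cls - 1].push_back(id);
    if (footprint > 0) occ[(size_t)tr * L + (pos - 1)] = 1;
    return id;
  };
  auto remove_from_class = [&](int id) {
    int cls = rib_cls[id], slot = rib_slot[id];
    std::vector<int>& v = cls_members[cls - 1];
    int last = v.back();
    v[slot] = last; rib_slot[last] = slot;
    v.pop_back();
  };
  auto blocked = [&](int tr, int from_excl, int to_incl) {
    // any ribosome head in (from_excl, to_incl] on transcript tr?
    int hi = to_incl > L ? L : to_incl;
    for (int p = from_excl + 1; p <= hi; ++p) {
      if (occ[(size_t)tr * L + (p - 1)]) return true;
    }
    return false;
  };

  RNGScope scope;
  for (;;) {
    const double n1 = (double)cls_members[0].size(),
                 n2 = (double)cls_members[1].size();
    const double a1 = k_charge * Tu1, a2 = k_charge * Tu2,
                 a3 = k_bind * (double)N * Rf,
                 a4 = k_speed * n1 * Tc1, a5 = k_speed * n2 * Tc2;
    const double a0 = a1 + a2 + a3 + a4 + a5;
    const double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    while (irec < n_rec && next_rec <= t_next) {
      rec(irec, 0) = next_rec;
      rec(irec, 1) = Tc1; rec(irec, 2) = Tc2;
      rec(irec, 3) = Tu1; rec(irec, 4) = Tu2;
      rec(irec, 5) = Rf;  rec(irec, 6) = n1; rec(irec, 7) = n2;
      rec(irec, 8) = protein;
      ++irec;
      next_rec = (double)irec * record_interval;
    }
    if (irec >= n_rec || !(a0 > 0.0)) break;
    t = t_next;
    const double u = unif_rand() * a0;
    if (u < a1) {
      Tu1 -= 1; Tc1 += 1;
    } else if (u < a1 + a2) {
      Tu2 -= 1; Tc2 += 1;
    } else if (u < a1 + a2 + a3) {
      int tr = (int)(unif_rand() * N);
      if (tr == N) tr = N - 1;
      if (footprint > 0 && blocked(tr, 0, footprint)) continue; // null event
      Rf -= 1;
      add_rib(tr, 1);
    } else {
      const int cls = (u < a1 + a2 + a3 + a4) ? 1 : 2;
      std::vector<int>& v = cls_members[cls - 1];
      int k = (int)(unif_rand() * v.size());
      if (k == (int)v.size()) k = (int)v.size() - 1;
      const int id = v[k];
      const int tr = rib_tr[id], pos = rib_pos[id];
      if (pos < L && footprint > 0 && blocked(tr, pos, pos + footprint)) {
        continue; // sterically blocked: true propensity is zero (thinning)
      }
      // consume one charged tRNA of this class
      if (cls == 1) { Tc1 -= 1; Tu1 += 1; } else { Tc2 -= 1; Tu2 += 1; }
      if (footprint > 0) occ[(size_t)tr * L + (pos - 1)] = 0;
      remove_from_class(id);
      if (pos == L) { // stepping past the last codon: terminate
        free_ids.push_back(id);
        Rf += 1; protein += 1;
      } else {
        const int npos = pos + 1;
        const int ncls = seqs(tr, npos - 1);
        rib_pos[id] = npos; rib_cls[id] = ncls;
        rib_slot[id] = (int)cls_members[ncls - 1].size();
        cls_members[ncls - 1].push_back(id);
        if (footprint > 0) occ[(size_t)tr * L + (npos - 1)] = 1;
      }
    }
  }
  colnames(rec) = CharacterVector::create("time", "T_c1", "T_c2", "T_u1",
                                          "T_u2", "R_f", "R_b1", "R_b2",
                                          "protein");
  return rec;
}
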