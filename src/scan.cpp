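#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// standard genetic code, codon index = 16*b1 + 4*b2 + b3 with A=0,C=1,G=2,T=3
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

// Translate one reading frame of seq (offset f) into amino acids; 'X' for
// codons containing non-ACGT bases, '*' for stops.
static void translate_frame(const std::string &seq, int f, std::string &out) {
  out.clear();
  int n = (int)seq.size();
  for (int i = f; i + 2 < n; i += 3) {
    int b1 = base2bits(seq[i]), b2 = base2bits(seq[i + 1]), b3 = base2bits(seq[i + 2]);
    if (b1 < 0 || b2 < 0 || b3 < 0) out.push_back('X');
    else out.push_back(CODON_TABLE[16 * b1 + 4 * b2 + b3]);
  }
}

// Ungapped sliding-window scan of all six frames of each contig against a
// position-specific score matrix (rows = residues in aa_order, cols = window
// positions). Windows containing a stop codon or untranslatable residue are
// voided. Returns every window scoring >= score_min.
// [[Rcpp::export]]
List scan_profile_cpp(CharacterVector contigs, NumericMatrix score_mat,
                      std::string aa_order, double score_min) {
  const int L = score_mat.ncol();
  const int n_aa = score_mat.nrow();
  int aa_row[128];
  for (int i = 0; i < 128; ++i) aa_row[i] = -1;
  for (int i = 0; i < n_aa; ++i) aa_row[(unsigned char)aa_order[i]] = i;

  std::vector<int> out_contig, out_frame, out_aaoff;
  std::vector<char> out_strand;
  std::vector<double> out_score;
  std::vector<std::string> out_pep;
  double n_windows = 0.0;  // valid (non-voided) windows scanned

  std::string aa;
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    std::string seq = as<std::string>(contigs[ci]);
    std::string rc(seq.rbegin(), seq.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = comp(rc[i]);

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = (strand == 0) ? seq : rc;
      for (int f = 0; f < 3; ++f) {
        translate_frame(s, f, aa);
        int m = (int)aa.size();
        if (m < L) continue;
        // residue row per position; prefix count of untranslatable positions
        std::vector<int> rows(m);
        std::vector<int> bad(m + 1, 0);
        for (int i = 0; i < m; ++i) {
          rows[i] = aa_row[(unsigned char)aa[i]];
          bad[i + 1] = bad[i] + (rows[i] < 0 ? 1 : 0);
        }
        for (int w = 0; w + L <= m; ++w) {
          if (bad[w + L] - bad[w] > 0) continue;
          n_windows += 1.0;
          double sc = 0.0;
          for (int j = 0; j < L; ++j) sc += score_mat(rows[w + j], j);
          if (sc >= score_min) {
            out_contig.push_back((int)ci + 1);
            out_strand.push_back(strand == 0 ? '+' : '-');
            out_frame.push_back(f);
            out_aaoff.push_back(w);
            out_score.push_back(sc);
            out_pep.push_back(aa.substr(w, L));
          }
        }
      }
    }
  }

  int nh = (int)out_score.size();
  IntegerVector contig(nh), frame(nh), aaoff(nh);
  CharacterVector strand(nh), pep(nh);
  NumericVector score(nh);
  for (int i = 0; i < nh; ++i) {
    contig[i] = out_contig[i];
    frame[i] = out_frame[i];
    aaoff[i] = out_aaoff[i];
    strand[i] = std::string(1, out_strand[i]);
    score[i] = out_score[i];
    pep[i] = out_pep[i];
  }
  return List::create(_["contig"] = contig, _["strand"] = strand,
                      _["frame"] = frame, _["aa_offset"] = aaoff,
                      _["score"] = score, _["peptide"] = pep,
                      _["n_windows"] = n_windows);
}
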