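# SYNTHETIC reference CDR3 list (21 sequences).
# Stand-in sequences for testing the exact-match workflow; these are
# randomly generated CDR3-beta-like strings, NOT the published
# experimentally confirmed KRAS-mutant-specific sequences, which are
# distributed with their original publications. Supply the real list
# as a plain-text file (one sequence per line) for production use.
CASSLDRVGNTIYF
CASSFGREQYF
CASSPDRGSYEQYF
CASSQDLNTGELFF
CASSLGQAYEQYF
CASSPGTSGSYNEQFF
CASSYSDRGNQPQHF
CASSLTGGRNTEAFF
CASSIRSSYEQYF
CASSDPLGGYTF
CASSVDGYGYTF
CASSLEGQGFNEQFF
CASSPRDRGHEQYF
CASSLSFGTEAFF
CASSQEWGGELFF
CASSARTGELFF
CASSLLGGWSEAFF
CASSFPTSGGYNEQFF
CASSQGRDTQYF
CASSLNRDSSYEQYF
CASSETGGTEAFF
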