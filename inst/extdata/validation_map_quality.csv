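pdb,reproduction_sitemap,reproduction_top_pose,correctness_sitemap,correctness_top_pose
1Q9Q,0.88,0.88,0.64,0.88
1Q9T,1.00,1.00,0.80,0.80
3HZK,1.00,1.00,0.67,0.73
3HZV,1.00,1.00,0.75,0.90
3HZY,0.80,0.50,0.73,0.71
3OKK,0.86,1.00,0.55,0.88
3OKL,0.78,0.78,0.78,0.78
3OKN,1.00,1.00,0.67,0.80
3OKO,1.00,0.89,0.75,0.88
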