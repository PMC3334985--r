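pdb,program,top_rmsd,best_rmsd,best_rank
1Q9Q,glide,6.5,3.7,15
1Q9T,glide,4.8,1.5,7
3HZK,glide,4.9,1.3,12
3HZV,glide,5.0,3.0,4
3HZY,glide,8.4,1.2,11
3OKK,glide,6.6,1.0,11
3OKL,glide,5.8,3.3,15
3OKN,glide,8.2,1.7,11
3OKO,glide,7.1,2.1,62
1Q9Q,gold,6.8,4.3,2
1Q9T,gold,3.4,1.0,5
3HZK,gold,1.6,1.5,7
3HZV,gold,1.1,1.1,1
3HZY,gold,1.5,1.2,4
3OKK,gold,1.2,1.2,1
3OKL,gold,6.6,0.8,2
3OKN,gold,3.0,1.3,8
3OKO,gold,6.2,3.5,58
1Q9Q,autodock,6.3,3.7,27
1Q9T,autodock,7.3,1.9,3
3HZK,autodock,3.5,3.4,10
3HZV,autodock,6.6,3.1,81
3HZY,autodock,8.6,3.2,48
3OKK,autodock,1.9,1.9,1
3OKL,autodock,3.6,1.5,2
3OKN,autodock,7.5,4.1,30
3OKO,autodock,4.5,3.8,46
1Q9Q,dock,9.8,5.7,7
1Q9T,dock,5.0,2.0,4
3HZK,dock,4.6,1.3,11
3HZV,dock,NA,NA,NA
3HZY,dock,8.1,6.3,3
3OKK,dock,5.5,3.6,11
3OKL,dock,5.5,4.6,6
3OKN,dock,6.4,6.4,1
3OKO,dock,NA,NA,NA
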