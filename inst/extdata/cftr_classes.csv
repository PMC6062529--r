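mutation,class
G542X,1
W1282X,1
1717-1G->A,1
N1303K,2
F508del,2
A455E,2
G551D,3
R117H,3
F508del,3
R117H,4
R347H,4
R347P,4
R334W,4
621+1G->T,5
3849+10kbC->T,5
2789+5G->A,5
F508del,6
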