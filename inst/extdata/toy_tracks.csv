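day,cell_id,parent_id,x_um,y_um,z_um,event,labels
0,1,,20,40,55,none,
0,2,,50,40,60,none,
0,3,,80,40,65,none,
0,4,,110,40,70,none,
0,5,,140,40,75,none,
0,6,,20,100,80,none,
0,7,,50,100,85,none,
0,8,,80,100,90,none,
0,9,,110,100,95,none,
0,10,,140,100,100,none,
1,1,,20,40,55,none,
1,2,,50,40,60,none,
1,3,,80,40,65,none,
1,4,,110,40,70,none,
1,5,,140,40,75,none,
1,6,,20,100,80,none,
1,7,,50,100,85,none,
1,8,,80,100,90,none,
1,9,,110,100,95,none,
1,10,,140,100,100,none,
2,1,,20,40,55,none,
2,2,,50,40,60,none,
2,3,,80,40,65,divided,
2,4,,110,40,70,none,
2,5,,140,40,75,none,
2,6,,20,100,80,none,
2,7,,50,100,85,none,
2,8,,80,100,90,none,
2,9,,110,100,95,none,
2,10,,140,100,100,none,
3,1,,20,40,55,none,
3,2,,50,40,60,none,
3,4,,110,40,70,none,
3,5,,140,40,75,none,
3,6,,20,100,80,none,
3,7,,50,100,85,none,
3,8,,80,100,90,none,
3,9,,110,100,95,none,
3,10,,140,100,100,none,
3,11,3,77,40,65,appeared,
3,12,3,83,40,65,appeared,
4,1,,20,40,55,none,
4,2,,50,40,60,none,
4,4,,110,40,70,none,
4,5,,140,40,75,none,
4,6,,20,100,80,none,
4,7,,50,100,85,died,
4,8,,80,100,90,none,
4,9,,110,100,95,none,
4,10,,140,100,100,none,
4,11,3,77,40,65,none,
4,12,3,83,40,65,none,
5,1,,20,40,55,none,
5,2,,50,40,60,none,
5,4,,110,40,70,none,
5,5,,140,40,75,none,
5,6,,20,100,80,none,
5,8,,80,100,90,none,
5,9,,110,100,95,none,
5,10,,140,100,100,none,
5,11,3,77,40,65,none,
5,12,3,83,40,65,none,
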