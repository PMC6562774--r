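subset,original,predicted,count
A-B,A,A,97
A-B,B,A,6
A-B,A,B,3
A-B,B,B,94
A-C,A,A,94
A-C,C,A,1
A-C,A,C,6
A-C,C,C,99
A-D,A,A,100
A-D,D,A,0
A-D,A,D,0
A-D,D,D,100
A-E,A,A,100
A-E,E,A,1
A-E,A,E,0
A-E,E,E,99
B-C,B,B,99
B-C,C,B,1
B-C,B,C,1
B-C,C,C,99
B-D,B,B,100
B-D,D,B,0
B-D,B,D,0
B-D,D,D,100
B-E,B,B,100
B-E,E,B,1
B-E,B,E,0
B-E,E,E,99
C-D,C,C,88
C-D,D,C,28
C-D,C,D,12
C-D,D,D,72
C-E,C,C,99
C-E,E,C,2
C-E,C,E,1
C-E,E,E,98
D-E,D,D,99
D-E,E,D,2
D-E,D,E,1
D-E,E,E,98
A-B-C,A,A,92
A-B-C,B,A,5
A-B-C,C,A,2
A-B-C,A,B,3
A-B-C,B,B,95
A-B-C,C,B,0
A-B-C,A,C,5
A-B-C,B,C,0
A-B-C,C,C,98
A-B-D,A,A,96
A-B-D,B,A,4
A-B-D,D,A,1
A-B-D,A,B,2
A-B-D,B,B,95
A-B-D,D,B,0
A-B-D,A,D,2
A-B-D,B,D,1
A-B-D,D,D,99
A-B-E,A,A,96
A-B-E,B,A,5
A-B-E,E,A,3
A-B-E,A,B,4
A-B-E,B,B,95
A-B-E,E,B,1
A-B-E,A,E,0
A-B-E,B,E,0
A-B-E,E,E,96
A-C-D,A,A,94
A-C-D,C,A,2
A-C-D,D,A,1
A-C-D,A,C,4
A-C-D,C,C,87
A-C-D,D,C,16
A-C-D,A,D,2
A-C-D,C,D,11
A-C-D,D,D,83
A-C-E,A,A,96
A-C-E,C,A,3
A-C-E,E,A,1
A-C-E,A,C,4
A-C-E,C,C,97
A-C-E,E,C,16
A-C-E,A,E,0
A-C-E,C,E,0
A-C-E,E,E,83
B-C-D,B,B,98
B-C-D,C,B,1
B-C-D,D,B,1
B-C-D,B,C,1
B-C-D,C,C,91
B-C-D,D,C,14
B-C-D,B,D,1
B-C-D,C,D,8
B-C-D,D,D,85
B-C-E,B,B,100
B-C-E,C,B,1
B-C-E,E,B,2
B-C-E,B,C,0
B-C-E,C,C,99
B-C-E,E,C,1
B-C-E,B,E,0
B-C-E,C,E,0
B-C-E,E,E,97
B-D-E,B,B,100
B-D-E,D,B,1
B-D-E,E,B,2
B-D-E,B,D,0
B-D-E,D,D,98
B-D-E,E,D,2
B-D-E,B,E,0
B-D-E,D,E,1
B-D-E,E,E,96
D-C-E,D,D,82
D-C-E,C,D,10
D-C-E,E,D,1
D-C-E,D,C,17
D-C-E,C,C,88
D-C-E,E,C,16
D-C-E,D,E,1
D-C-E,C,E,2
D-C-E,E,E,83
A-D-E,A,A,100
A-D-E,D,A,2
A-D-E,E,A,1
A-D-E,A,D,0
A-D-E,D,D,98
A-D-E,E,D,0
A-D-E,A,E,0
A-D-E,D,E,0
A-D-E,E,E,99
A-C-D-E,A,A,98
A-C-D-E,C,A,4
A-C-D-E,D,A,5
A-C-D-E,E,A,1
A-C-D-E,A,C,1
A-C-D-E,C,C,81
A-C-D-E,D,C,9
A-C-D-E,E,C,0
A-C-D-E,A,D,1
A-C-D-E,C,D,15
A-C-D-E,D,D,85
A-C-D-E,E,D,1
A-C-D-E,A,E,0
A-C-D-E,C,E,0
A-C-D-E,D,E,1
A-C-D-E,E,E,98
B-C-D-E,B,B,98
B-C-D-E,C,B,1
B-C-D-E,D,B,0
B-C-D-E,E,B,2
B-C-D-E,B,C,1
B-C-D-E,C,C,86
B-C-D-E,D,C,13
B-C-D-E,E,C,0
B-C-D-E,B,D,1
B-C-D-E,C,D,13
B-C-D-E,D,D,84
B-C-D-E,E,D,0
B-C-D-E,B,E,0
B-C-D-E,C,E,0
B-C-D-E,D,E,3
B-C-D-E,E,E,98
A-B-C-D-E,A,A,95
A-B-C-D-E,B,A,3
A-B-C-D-E,C,A,1
A-B-C-D-E,D,A,0
A-B-C-D-E,E,A,1
A-B-C-D-E,A,B,3
A-B-C-D-E,B,B,97
A-B-C-D-E,C,B,1
A-B-C-D-E,D,B,0
A-B-C-D-E,E,B,0
A-B-C-D-E,A,C,0
A-B-C-D-E,B,C,0
A-B-C-D-E,C,C,87
A-B-C-D-E,D,C,10
A-B-C-D-E,E,C,0
A-B-C-D-E,A,D,0
A-B-C-D-E,B,D,0
A-B-C-D-E,C,D,11
A-B-C-D-E,D,D,90
A-B-C-D-E,E,D,0
A-B-C-D-E,A,E,2
A-B-C-D-E,B,E,0
A-B-C-D-E,C,E,0
A-B-C-D-E,D,E,0
A-B-C-D-E,E,E,99
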