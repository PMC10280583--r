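-1.03317345916
-0.963130916055
-0.883466890199
-0.921437697446
-0.976425412153
-0.85233993912
-0.443212156037
0.212404866364
0.798770173999
1.05891149945
0.923470576247
0.306021136582
-0.406572330051
-0.696505722505
-0.744272392065
-0.828907801503
-0.923667247791
-0.860070642993
-0.699924877692
-0.484016237519
-0.06509826567
0.811418126774
1.87838418075
2.13344132724
1.41790109901
0.934635133797
1.28344149968
1.56558962612
0.828919477149
-0.384550617124
-0.935440105506
-1.05109601256
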