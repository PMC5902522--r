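"value","group"
-2.0274,"boys"
3.6143,"boys"
2.0005,"boys"
3.2536,"boys"
-0.2477,"boys"
0.5158,"boys"
0.7047,"boys"
-0.9962,"boys"
0.8402,"boys"
-0.3414,"boys"
1.5786,"boys"
-1.1232,"boys"
-0.0466,"boys"
1.7362,"boys"
-0.4556,"boys"
1.0188,"boys"
1.9669,"boys"
0.5734,"boys"
-0.9167,"boys"
0.8515,"boys"
-0.9247,"girls"
0.1473,"girls"
-1.3248,"girls"
-0.1068,"girls"
0.0202,"girls"
0.8091,"girls"
-1.3922,"girls"
0.3938,"girls"
1.9963,"girls"
2.3573,"girls"
-0.4451,"girls"
-0.858,"girls"
-0.1274,"girls"
-1.8772,"girls"
2.42,"girls"
-0.8602,"girls"
-0.7405,"girls"
-0.3885,"girls"
-0.5499,"girls"
0.5725,"girls"
-0.1103,"girls"
1.0119,"girls"
-0.2412,"girls"
0.1879,"girls"
0.8322,"girls"
0.5056,"girls"
-1.2156,"girls"
-1.0181,"girls"
-0.4305,"girls"
0.045,"girls"
-0.9225,"girls"
0.6122,"girls"
0.0853,"girls"
0.4811,"girls"
0.2096,"girls"
-0.4242,"girls"
0.794,"girls"
0.9115,"girls"
-1.3383,"girls"
-0.1824,"girls"
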