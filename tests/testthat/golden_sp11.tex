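% Edmundson wheel: SP1-1
\begin{tikzpicture}
  \draw[thin, gray] (0,0) circle (5.0000);
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (0.0000,5.0000) {R1};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (4.9240,-0.8682) {K2};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (-1.7101,-4.6985) {K3};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (-4.3301,2.5000) {R4};
  \node[circle, draw, minimum size=7mm, fill=red] at (3.2139,3.8302) {L5};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (3.2139,-3.8302) {K6};
  \node[circle, draw, minimum size=7mm, fill=red] at (-4.3301,-2.5000) {L7};
  \node[circle, draw, minimum size=7mm, fill=red] at (-1.7101,4.6985) {L8};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (4.9240,0.8682) {K9};
  \node[circle, draw, minimum size=7mm, fill=blue!80!black] at (0.0000,-5.0000) {R10};
  \node[circle, draw, minimum size=7mm, fill=red] at (-4.9240,0.8682) {L11};
  \draw[->, very thick] (0,0) -- (-2.8333,2.6480);
\end{tikzpicture}
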